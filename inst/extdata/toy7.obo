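format-version: 1.2
ontology: synthetic-toy7

[Term]
id: GO:0100001
name: synthetic root
namespace: molecular_function

[Term]
id: GO:0100002
name: synthetic binding
namespace: molecular_function
is_a: GO:0100001

[Term]
id: GO:0100003
name: synthetic catalysis
namespace: molecular_function
is_a: GO:0100001

[Term]
id: GO:0100004
name: synthetic ion binding
namespace: molecular_function
is_a: GO:0100002

[Term]
id: GO:0100005
name: synthetic protein binding
namespace: molecular_function
is_a: GO:0100002

[Term]
id: GO:0100006
name: synthetic hydrolase
namespace: molecular_function
is_a: GO:0100003

[Term]
id: GO:0100007
name: synthetic ion-dependent hydrolase
namespace: molecular_function
is_a: GO:0100004
is_a: GO:0100006

[Term]
id: GO:0100008
name: obsolete synthetic activity
namespace: molecular_function
is_obsolete: true

[Term]
id: GO:0200001
name: synthetic other-namespace term
namespace: biological_process
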