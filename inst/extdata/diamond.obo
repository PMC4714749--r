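format-version: 1.2
ontology: synthetic-diamond

[Term]
id: GO:0000001
name: synthetic root activity
namespace: molecular_function

[Term]
id: GO:0000002
name: synthetic parent activity A
namespace: molecular_function
is_a: GO:0000001 ! synthetic root activity

[Term]
id: GO:0000003
name: synthetic parent activity B
namespace: molecular_function
is_a: GO:0000001 ! synthetic root activity

[Term]
id: GO:0000004
name: synthetic multi-parent child activity
namespace: molecular_function
is_a: GO:0000002 ! synthetic parent activity A
is_a: GO:0000003 ! synthetic parent activity B
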