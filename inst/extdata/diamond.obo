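format-version: 1.2

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:7000001
name: diamond term a
namespace: molecular_function
is_a: GO:0003674

[Term]
id: GO:7000002
name: diamond term b
namespace: molecular_function
is_a: GO:7000001

[Term]
id: GO:7000003
name: diamond term c
namespace: molecular_function
is_a: GO:7000001

[Term]
id: GO:7000004
name: diamond term d
namespace: molecular_function
is_a: GO:7000002
is_a: GO:7000003

[Term]
id: GO:7000099
name: obsolete diamond term
namespace: molecular_function
is_obsolete: true
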