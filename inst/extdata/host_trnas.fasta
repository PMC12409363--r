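>Eco-Lys-UUU aa=Lys source=host note=synthetic-reconstruction
GGGUCGUUAGCUCAGUUGGUAGAGCAGUUGACUUUUAAUCAAUGGGUCGCAGGUUCGAAUCCUGCACGACCCACCA
>Eco-Thr-UGU aa=Thr source=host note=synthetic-reconstruction
GGCUCGUUAGCUCAGUUGGUAGAGCAGUUGACUUGUAAUCAAUGGGACGCAGGUUCGAGUCCUGCACGAGCCACCA
>Eco-Asn-GUU aa=Asn source=host note=synthetic-reconstruction
GGGCCGUUAGCUCAGUUGGUAGAGCAGUGGACUGUUAAUCCAUGGGUUGCAGGUUCGACUCCUGCACGGCCCACCA
>Eco-Thr-CGU aa=Thr source=host note=synthetic-reconstruction
GCGUCGUUAGCUCAGUUGGUAGAGCAGUGCACUCGUAAUGCAUGGGGCGCAGGUUCGACUCCUGCACGACGCACCA
>Eco-Phe-GAA aa=Phe source=host note=synthetic-reconstruction
GCCCGGAUAGCUCAGUCGGUAGAGCAGGGGAUUGAAAAUCCCCGUGUCCUUGGUUCGAUUCCGAGUCCGGGCACCA
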