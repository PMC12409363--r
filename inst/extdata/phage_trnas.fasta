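>T5-Lys-UUU aa=Lys source=phage note=synthetic-reconstruction
GGGUUGUUAGCUCAGCUGGUAGAGCAGUUGACUUUUAAACCAUGGGUCGCAGGUUCGAAUCCUGCACAACCCACCA
>T5-Thr-UGU aa=Thr source=phage note=synthetic-reconstruction
GGCUCAUUAGCUCAGUUGGUAGAGCAGUUGACUUGUAAACCAUGGGACGCAGGUUCGAGUCCUGCAUGAGCCACCA
>T5-Asn-GUU aa=Asn source=phage note=synthetic-reconstruction
GGGCCGCUAGCUCAGUUGGUAGAGCAGUGGACUGUUAAACCAUGGGUUGCAGGUUCGACUCCUGCGCGGCCCACCA
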