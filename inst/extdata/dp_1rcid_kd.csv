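# Dissociation constants (ITC, 25 C) between ancestral deuterostome/
# protostome (D/P) NCBD variants and 1R CID variants, in uM, with fit
# standard errors. Ten measurements over alternative residues at the
# uncertain reconstructed positions.
ncbd_variant,cid_variant,kd_uM,se_uM
D/P NCBD,1R CID,3.0,0.13
D/P NCBD,1R CID S1058N,3.9,0.16
D/P NCBD,1R CID G1080S,4.8,0.20
D/P NCBD,1R CID S1078Q,5.5,0.21
D/P NCBD T2062I,1R CID,2.0,0.2
D/P NCBD T2062V,1R CID,2.2,0.6
D/P NCBD P2063L,1R CID,7.7,0.53
D/P NCBD Q2088H,1R CID,1.5,0.080
D/P NCBD Q2088N,1R CID,2.2,0.070
D/P NCBD H2107Q,1R CID,18,1.2
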