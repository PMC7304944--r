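root R
edge R Outgroup 0.08
edge R anc1 0.02
edge anc1 NorthAmerica 0.04
edge anc1 anc2 0.03
edge anc2 Amazon 0.05
edge anc2 anc3 0.02
edge anc3 ancH 0.02
edge anc3 ancC 0.02
edge ancH HighlandsNorth 0.02
edge ancH hsAnc 0.01
edge hsAnc HighlandsSouth 0.01
edge ancC CoastNorth 0.02
edge ancC csAnc 0.01
edge csAnc CoastSouth 0.01
edge Madm Admixed 0.01
admix Madm hsAnc csAnc 0.5
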