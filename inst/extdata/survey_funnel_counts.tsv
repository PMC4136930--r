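stage	v4_reads	v9_reads	v4_otus	v9_otus
all	1476249	195944951	NA	NA
diatoms	202834	14197290	NA	NA
putative	51378	1526145	51	844
after_rare	50718	1525527	12	403
final	50718	466070	12	157
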