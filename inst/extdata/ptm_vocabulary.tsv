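label	residues	synonyms
phosphorylation	S;T;Y	phospho;phosphorylated;phosphorylation site;p-site
acetylation	K	acetyl;acetylated;n6-acetyllysine
ubiquitination	K	ubiquitin;ubiquitylation;ubiquitinated
methylation	K;R	methyl;methylated;mono-methylation;dimethylation;trimethylation
sumoylation	K	sumo;sumoylated
glycosylation	N;S;T	glycosyl;o-glcnac;n-linked glycosylation;o-linked glycosylation
oxidation	C;M	oxidized;oxidation site
sulfenic acid	C	sulfenylation;cysteine sulfenic acid
nitrosylation	C	s-nitrosylation;nitrosylated
palmitoylation	C	s-palmitoylation;palmitoylated
hydroxylation	P;K	hydroxyl;hydroxylated
succinylation	K	succinyl;n6-succinyllysine
citrullination	R	citrulline;deimination
myristoylation	G	n-myristoylation
malonylation	K	n6-malonyllysine;malonyl
caspase cleavage	D	caspase;caspase site
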