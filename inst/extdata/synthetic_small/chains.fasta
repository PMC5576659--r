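>syn0001
FHDDLGATEPITWEPMGDAVSLEFEIRIGQDNATSNDNHKEHDETIFSGLAVKDHYDDEDVIPLFEQEEI
EFEPHSTSEPGTAGAGLDFPNISNRDEVWD
>syn0002
HESMAMEKKTSAEDLQGPAERVDIMQEVQSVALTDYVMGNGLFTMDQESKLGRPFENLRERYGEDPKQDI
SCDVVNPAKRISSLYLINRSKNAHIMYPDD
>syn0003
SSYAARLLPMGDEHNPGLEPMDTQTESDAPLVSMCLRLKADNEALEWKEVELLFSISTSILVHKHNPLAA
PYSGEIYLAPVTGSIMLVGEPFDDANTMLR
>syn0004
EFVSRRRGNLDSEPAIPIIRRDFSHEAGMLGLEGEDSEYAVGPMIDARFILGVVLERKRIAHPEAGPLRA
PWARKNERLRKSHTVYSNPSKKHLPFWHDL
>syn0005
EINSVMLQSDPVAFSPAEKVSSISVDGNNRKLSDLFALPLENAEETESVHTFMPQNFQEFNAAMSLCLIS
EPVDPTCHEDSKCHGSPTETAFFALEERIE
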