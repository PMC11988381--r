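compound,cas_id,CAR,AR,PXR,PPARa,PPARg,PPARd,RORgt
Dimethyl phthalate,131-11-3,#N/A,#N/A,-6.7,#N/A,#N/A,#N/A,#N/A
Diethyl phthalate,84-66-2,-6.7,-6.3,-6.8,-6.3,-6.7,-6.1,-6.6
Diallyl phthalate,131-17-9,-7.2,-6.5,-6.9,-6.7,-7.5,-6.6,-6.6
Di-n-propyl phthalate,131-16-8,-7.2,-6.4,-6.8,-6.5,-7.3,-6.3,-6.4
Di-n-butyl phthalate,84-74-2,-6.8,-6.9,-6.7,-6.9,-7.1,-6.7,-7.3
Diisobutyl phthalate,84-69-5,-7.7,-7.3,-7.3,-7,-7.6,-7,-7.3
Di-2-methoxyethyl phthalate,117-82-8,-6.6,-6.2,-6.7,-6.5,-6.9,-6,-6.3
Butyl cyclohexyl phthalate,84-64-0,-8,-7.9,-7.9,-7.5,-8.1,-7.8,-8
Di-n-pentyl phthalate,131-18-0,-7.4,-7,-7.2,-6.8,-7.5,-7.2,-5.4
Dicyclohexyl phthalate,84-61-7,-9.7,-8.7,-8.6,-8.6,-9,-9.3,-9.4
Butyl benzyl phthalate,85-68-7,-8.4,-7.8,-8.2,-8.2,-8.8,-8.3,-7.9
Di-n-hexyl phthalate,84-75-3,-6.9,-7.1,-7,-6.9,-7.2,-7.4,-7.6
Diisohexyl phthalate,146-50-9,-8.2,-7.3,-7.7,-7.4,-8.2,-7.9,-7.6
Diisoheptyl phthalate,41451-28-9,-8,-7,-8.1,-7.2,-8,-8.2,-8
Butyl decyl phthalate,89-19-0,-7.9,-6.9,-7.4,-7.3,-7.5,-7.4,-7.5
Dibutoxy ethyl phthalate,117-83-9,-6.9,-7,-7,-7.3,-7.1,-7.2,-7.4
Di(2-ethylhexyl) phthalate,117-81-7,-8,-5.9,-8,-7.5,-7.8,-7.9,-8.5
Di(n-octyl) phthalate,117-84-0,-8,-7.3,-7.3,-7.5,-7.7,-7.7,-7.8
Diisooctyl phthalate,27554-26-3,-8.2,-7.6,-8,-7.4,-7.8,-8.2,-8.3
n-Octyl n-decyl phthalate,119-07-3,#N/A,#N/A,-7.3,#N/A,#N/A,#N/A,#N/A
Diisononyl phthalate,28553-12-0,-7.9,-8,-7.7,-7.5,-7.6,-8.3,-8
Di(2-propylheptyl) phthalate,53306-54-0,-7.9,-6.9,-7.9,-7.5,-7.8,-7.8,-8.3
Diisodecyl phthalate,26761-40-0,-7.6,-7.5,-8,-7.9,-7.7,-8.1,-8.5
Diundecyl phthalate,3648-20-2,-6.7,-7.4,-7.1,-7.3,-7.4,-7.7,-7.8
Diisoundecyl phthalate,85507-79-5,-7.7,-7.3,-8.3,-7.8,-7.7,-8,-8.5
Ditridecyl phthalate,119-06-2,#N/A,#N/A,-6.9,#N/A,#N/A,#N/A,#N/A
Diisotridecyl phthalate,68515-47-9,-7.4,-7.3,-7.5,-8,-8,-8.3,-8.2
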