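compound,epa_id,CAR,AR,PXR,PPARa,PPARg,PPARd,RORgt
Acifluorfen-sodium,114402,-8.8,-7.5,-8.5,-8,-8.9,-8.9,-9.2
Bifenthrin,128825,-9.6,-5.5,-10,-10.3,-10.1,-10.9,-9.5
Bromethalin,112802,-8.1,-7.2,-7.6,-5.7,-7.4,-5.8,-6.2
Chlorfenapyr,129093,-8.1,-7.8,-7.4,-6.4,-6.9,-7.6,-7.4
Cyflufenamid,555550,-9.1,-5.9,-9.4,-8.2,-10.1,-8.7,-7.4
Cyflumetofen,138831,-7.1,-5.9,-8.1,-6.1,-7.9,-7.5,-7.2
Dithiopyr,128994,-8.2,-7.1,-6.3,-5.2,-6,-7,-6.2
Ethalfluralin,113101,-8,-8,-6.9,-6,-7.1,-7,-6.8
Fipronil,129121,-7.7,-7.7,-8.2,-7.1,-7.3,-8,-8.4
Fluazifop-P-butyl,122809,-7.7,-7.8,-8.7,-8.3,-8.3,-8.9,-9
Flufenacet,121903,-8.1,-8.1,-8.7,-7.9,-8.4,-8.2,-8
Fluridone,112900,-9.3,-8,-9.5,-9.6,-10,-9.9,-9.2
Flurprimidol,125701,-8,-9.1,-8.5,-6.8,-8.4,-7.6,-7.1
Flutolanil,128975,-8.8,-5.5,-8.6,-7.9,-8.5,-9.2,-9.3
Fluvalinate,109302,-8.7,#N/A,-10.4,-9.7,-10.3,-10.6,-10
Fomesafen,123802,#N/A,-7.1,#N/A,#N/A,#N/A,#N/A,#N/A
gamma-Cyhalothrin,128807,-10,-6.4,-9.7,-9,-9.3,-10.2,-7.8
Hexaflumuron,118202,-7.1,-7.1,#N/A,-9.6,-8.9,-9.8,-9.6
Hydramethylnon,118401,-7.1,-8.2,-10.4,-9.6,-10.2,-12.3,-8.9
Lactofen,128888,-8.1,-7,-9.1,-9.1,-9,-9.2,-8.7
lambda-Cyhalothrin,128897,#N/A,-8.8,-9.9,-8,-9.9,-10,-6.5
Norflurazon,105801,-8.4,-7.6,-8.3,-7.8,-8.3,-8.2,-8
Novaluron,124002,-7.4,-6.6,-10.7,-9.5,-10.3,-10.5,-10.4
Noviflumuron,118204,-7.8,-9.3,-10.8,-9.6,-9.4,-10.4,-10.8
Oxathiapiprolin,128111,-8,-9,-10.7,-9.2,-10.8,-11.6,-10.5
Oxyfluorfen,111601,-8.2,-6.1,-8.3,-7.9,-8.5,-8.6,-8.6
Penoxsulam,119031,-8.1,-7.3,-9.2,-7.7,-9,-7.7,-9.1
Picoxystrobin,129200,-9.4,-7.1,-8.3,-8.3,-7.7,-8.5,-7.4
Prodiamine,110201,-7.3,-5.9,-6.6,-5.9,-6.6,-6.6,-6.2
Prosulfuron,129031,-8.1,-9.5,-9.6,-8.4,-10,-8.9,-9.2
Pyridalyl,295149,-8.9,-8.5,-9.4,-8.5,-8.7,-9.3,-9.2
Pyrifluquinazon,555555,-9.2,-6.2,-9.7,-8.2,-10.3,-9.9,-8.5
Saflufenacil,118203,-6.6,-8.8,-10.6,-8.4,-9,-10.4,-8.9
Tefluthrin,128912,-9.2,-8,-9,-7.9,-9,-9.5,-9.9
Tetraconazole,120603,-8.1,-8.1,-8.1,-7.1,-7.9,-7.4,-7.8
Tralopyril,119093,-8.9,-8.2,-8,-7.2,-8.7,-7.9,-8.1
Trifloxystrobin,129112,-9.2,-7.3,-9.8,-9.2,-9.1,-8.8,-9.4
Triflumizole,128879,-8.7,-6.8,-7,-7.6,-7.3,-7.2,-7.6
Triflusulfuron-methyl,129002,-6.8,#N/A,-9.6,-8.9,-9.8,-8.8,-9
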