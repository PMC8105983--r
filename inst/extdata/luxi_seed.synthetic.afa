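>TraI_syn
MPLYQIPVSQLDRGGKMFGPRLEVRNDAFLIYKNWAYLAVFVFEAKVDDVKLASGYFKSVILATSELFNRCPEMVNGLQM
SLFPNKRWVAIPSVMLSESEGATRVKLHASMGNTLPKLRDPLTTAMANAKMLDNDKELIASVLLCVIFCSGVTKFKPCSQ
GTAGEFFPVLREEGGMVRKEGQASLLLGNQKSNGTGKLYEKLWIQPKSHPE
>LuxI_syn
MPLYQIPVSQLDRGGCIFGIRLEVRNDAFLIYKNWACLFHAVVEAKVTDVKLASPYFKSVILWYSPLLIRCPEMVNGLEM
SLFPEKRWVAIPSVMLPESEGATRFKLHASAFNTLPQLRYGPTTAMANAKELDNDKELIASVGLCVIFCSGVTKFKPCSQ
GTAGEFFLVLREEGGHVRKEIVASLLLG---SNPTGKLYEKLWIQVKSHRG
>LasI_syn
MPDYKSPVYQLDAGGKM--QFLEVRNDAFLIYKNWAVLANFVFEKKVDDVKLASGYFKSVILATSNLFNRCPEMVNGLQE
SLFPNKVIADIPSVRLSESWGATRVKLHTSMGNTLPEWRDPLTTHMANHKMLKPDKELIGSVLSCVIFCSGVTTFKPCLL
GCVGEFFMVLRETGGMVRKEGQASLLLGNQKSQGTGELYQKLSIQRWSEPF
>EsaI_syn
MPLYSIPVSAMDRGGTMFGPRLEVRRPAFLIYKNWPYLYGFVIEAINDDEKLADGYFKSVILATSELFNRCPEMNNDLQM
SLDPQDRWVA----MLSESEGATRVKLCDSMGNTLPKLRDPAPTAMANLKMLDNLKELIAKKFLCVIFCSGVYKDKPCSQ
GTAYEFHPVLRREGGVIRKQEQAQLKLGQFKSNTTRDLYEKLFIQPKSDPE
>RhlI_syn
MPLYFVTVSFLQRGGKKHGPRLVVRNDAFVFSWNWAYGAVFRFEAKGDDRKLCSTSFKSVIL--SELFHRCWEMVNGLQM
SLMPNRRHVAIPSVMLKESEELTRVKLPASMPNTLPKLRDPRTTAMDNLSCADNIKLLGAHVLLCVKYCSHVTKFHPCSQ
GTAGEFFPVLREEFGMIRKDGQAHLLLGQQKSTGTGHLYEGLWIRPKGHPE
>SinI_syn
MPLYQIPVFVIDRGGKMFGPKLEVRNTAFIIAKVWAYLAVFVFESFVDDVKLTSSYFKSVILRTSCLFNRCP--VNGSQM
SLFMNKRWVATIRVMLSESENATRVKLHASVVNTLQKLRDPLVTAMINAKMLDNDKELIQIGLLCVIFCSAVIKFKPCSM
LEAGTFFPVLREEGGMVRKEGQAVLELANQKSNGQGKLYEKHWKQPKSKWE
>CviI_syn
MPLLQMPVSQLDRGGHCFGPRLEARNDPFLIYKNWSMHAVEVFECKVDDVKCASGYFISAILACSELFNRGPPMVNGLQG
SSFP----VAIPWVMLSESGWATRVKLNCSMYNLLPKLRDPLTTAMAMMHMTDNDRDLIASVLVCVIFCSGSTFCKPCSQ
GTAGEFVPVLREEGGMHEKELQASLLLYNQISNGTGKLYEKLWIQPKSHPE
>PpnI_syn
MELIQIVVSQSCMGGKMFGPRLEVRVDAFPIYIRWAYLAVFVFEAKVDDVKLPSGYFKSVILADSTLFNRNFCMVNGLQM
SLFLNKEAELIKSVMPSESWVSTRVCLHAWMGGTMWKLSDPLTPAMANQKMLDNDKSITASVELCVI----VTKPKPCSQ
GTAGEWFTVLLEETGMVYNEGQESLLEGTHGSNGTGKLYEKLWHQPKSHPE
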