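>TraR_syn
MLRITGEIMVYLIPACITIFQQDVIGVIPSQLSLKVAGGALAGSDSVHLHGQDCLNWFRPYYKIPEKPIDPYVFEITGIL
NDATWGPLEIRLDELFDSGEFAVGYLAEPKGLGWVQIPEQNPATAVSGQSDQEPRFAYTIGEVKRADTGPNNPKAKTGED
EILLGVVSITWKAEAKNENVHLTLYSDGTLWKHTSFFYTLYTDSLPTAQDFMEQPFQSRPLKGYSWKKDTTARG
>LuxR_syn
MLRIKGEIMNHLIQACITIFQQDCWGVIGSQHSLKVAGQALEGSDSVCLHGCDCLYWCRFYYKIPEKPSDPCVFEIDGGL
NDASWGPLEIRLDEKFYSGEKAVGVLAAYKLLGWVQIPEQNPATAVAGQSDQEPRFAYTIG----ADTMPNKYFAKFGED
EITLGVVSITWQAEFKNENVHLFDYSDGTLWKHKAFFYTLYSDSLPTAQDFMLQPFQSRLLKGYSYVKDTTANG
>LasR_syn
MKSIRKESMVYLIPACITIFQQFVIGVIPSQWSLKVAIGALCFSDSVHMIGQGCLNWFRPYYVIPSKPIDPYVFEITGIL
NDATWSALRIDGDEKFDSHEFAY----YPKGLGWVLIPIQNPATAVSEQSNVERMQASYIKEMKRADQGNGNPKATTGED
YIILGVKSIFWKAEAKNEYEDLTLLSDGTLWPHTSEFYLLYTQMLPKAQVFMEQPFQPRPLKCERWKKDTTARG
>CviR_syn
MLRITGEVMVCLIPVCITICQFDVIKVIPDQLSLKVAGGVLVGSDSVHRHGQDCLNWFRPYYKIPEKPIDPYRFEITGIL
NNNTWGPIEIRADELFDSGYRAVGYLAEPKGLGWVVIPEQNPRTAVSGQSDQEPCFAYTIGEVKRAGTIPNNWTAKDGED
SL--GVVSFTWKAEAKNENVHLTLLQDGILEKSTSAFYTPKMDSDPTACDFMEQAFASRWLPGYSWKPDTTAGG
>SdiA_syn
MLRIHGEIMVPLIPACITTFQQDVIGV---QLSLKVAGGCLAGSDSVHLHGQDCLNWFQPYFKIPEKPIDPYVFEIHGIL
NDATWGPLEIRLDEMFDSGEFAVGYLAMPKGDGVQQIKCNNKYTAVSSTEDQEPRFQYTIGEVHRADRGPNNPHAKAGED
ETLLGVVSITWKAECKNENVKLTGYSDGVLCKHTSKPYTLYTDSLPTAQDFMEQNFQSIPLKGYSWKKNETACG
>ExpR_syn
MVRIDGEIMFYLIMACMTIFCQDHIGVIQQQLGLKVAGGAMAG--SEHLHGQDCSKWFQFYYKIPMKPIDPYVFNITLIL
NDATWGPGEIRLDELFDSGEFAVRLLAEHKGLGWVQWFEWYPWTAVSGFTDQEPRDAYTKWEVKRADTGPNMPWADTSED
EIMLGVVSRMWKAEANGENWFLTLYSDGTLKKHTMFTYLLYTSSLETAQDMMEQPFQSRPFKGYSWKKDTTARG
>NesR_syn
MNAIQGYIMLYLIPACIPPFQQDVIGVIPSQLSLKDAAGSVMGSWSSHLHWQDHLMWFREWYKIREKPIDPYVFEITGIL
QDATMFPGEIRLEELFNSGTFDVGYLAEPKGIGWVQIMEQNPLTEWSGQSD--LRFAYTIGEVERADTGFRNPSGKTGED
PFALGVVSITWRAEAKGENVHLTLYTDGTLWKKAMFFYELYTMFDPTAHGFMEQIFQSRPLKAYSWKKDTTARG
>XagR_syn
MLRWTGEIMVYLNPNCITIFHQQVIGVIPSQLSPKVAGGARAGSSSVHLHGQDCLNWQRPWDIIPPKPIDPYVFFITGIL
NDETMGPGECRLEELFDSGGFAVGRQSMPKGLGWVQIPEQNPRTYVSGWSDQLPRFAFTIGEVKRMNCGPNNPKMKTGED
KWLSGIVSWVWKAEKKNENVHLTLMSDGTLWKHTSFFSTLYTMSFE--QDFHEQPFQSRPLKGYTWKKDATARG
>OryR_syn
MLRITEFIMFYLIPACITIFQQCVIGNWPSVLSPKVAGGALAGSDSVHLHGQVCFNMFVPWYKIKEKPIDPYVFEITGIL
NDAHMGPLEICL----DSDEFAVGYLAEVKCLGWVQIPRQNCATALSGSSDQEPYFALTIGEVERADTGNNNPKGKTGED
EILLGVWSITKKLEAKNECVMLKLHSDGTLSKHTSYFYTLNTPCLPTADDFMYQPFQSRPLKGYSWKKDTTARG
>PsoR_syn
MLRITDYIMVYYPPAIITNFQKIVIGYIPSQLNLKQAGGILAPSDSVHLHGQDCLNWFLPWYFIPEKTIDPCVFEITGAL
ADATMGGLEIQTDLHFDPGEFAVGVLAEPKGCGWVQI--QNPALAHSDQCDQEPRFAYTIGEPARADTGPCNHLAKTGHD
EILLGVVSITWKFEAKNEGQHLTLYSDGTLWKHTSFFYTLYTISLPTAQDFMEQPFQSRNLKGYQKPKDTTAVK
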