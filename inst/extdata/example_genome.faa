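>gene_0001 taxon=self
IGWYVYWRHNLRTKNKYDAIDSKWCKLPCPMHTDFGQNLMGYMNSAKHECDVVNVYSEGI
LSQDSEDAEISCNFQDNPMQKGHMPTPGALTWHDSCAFLPTGVFYRMVMTPNVNAYSEYN
SFGVTCREDENTEQPKNNCNGWHQWHAAVLVSQLYNFEFLANMQHCWFYIMDFPSNRGRI
NPFLWICWQSTHQVMSQT
>gene_0002 taxon=self
IPWYAYWRHNLRSKDKYQAIDSKWCKLTCPMHTDMGTQRMGYMNSAKNEIDVVKVQSEGI
VSMDSEKYEISRNFQDNPMQCGIMPTPGALTWHDGYAFLPRLVFYTWVMTSNVNAYSFDN
MFGLTCREDENTEQPYNNCNGWHQWHAAVLVHQLYHYVHLANMQHCWKYIMQFKVVNGTI
NPFLWICWQSTASWCSQT
>gene_0003 taxon=self
VECVSIRRARGFETRGCRTWCIKRRVRHGTITETVHLLNATLIHFGSHFFCFGMEWCGPF
NPYRLLYAQAQCMNTYPYHMFLAHYNFNIVGMCWPHHDEIWPLMRQSMWHCHEGEKHNQF
QPPRPWWRPFSSCAVIRYMWHFYMELLGNPCPGAPPDPQPCVTRVQPVLDDPIEQISDCG
KISYHWWHK
>gene_0004 taxon=self
GIAEPKCKVDNLITLWMRYPMSGHGITHISITKDWAWQAVEGLFEYAMIDQNQWQKCECD
QVHLTAYTIVFRHFIEMPLAMSKNIDWCKCIGAHWTATHCNGGYMNSMMMIKWFGIFIVY
APCCLFVDWNQCMPHNFVKSMGFRNKHMPVNFENMHPDDKPASFYVFIIKYYIPYRGNVY
H
>gene_0005 taxon=self
GITEPKCKVDNVHTCFMRYTMSGHGITHESETKDWAWQPVEGLIDYAMIDGNKWSKCDTD
QRHLTFYCIVFRHFIEMHLGMSKNDWNMKNICAHWQPHHWQGGYMNDMMMWKVFGIFYVY
APCCLFVDWNQAKPLYFVKSMGFRNKEMPRNMENFHPDDKPASFYVFIHNCYIPYRGGGY
H
>gene_0006 taxon=self
EQSDCYGTHWPIEMTWLWKCREQKAAKVYEMRMNQFASRDGSTHICTMMWQLDEKWFEPE
LIGNNIRPPNMLSPQTCHCPSLAIAHPTWPFLAGFCKNTWRFGHPVHWVWDREFQQPPDC
GLKICDPHWVNHCPTGEHVLSVRTDFGRDHLDMSIHAWCYSPMVRDIIPDFGTTKLSAVC
PPMH
>gene_0007 taxon=self
VECVSIFRYRFFFPRGCRTWCIIIRVVHGIITELVHLLNATSIHFGCEFKCFGMEWEGEC
NPYRLLYASAQDMNTKPYHMFLASYMFQIVHMCAPHHSEIWVRMFQCNWHCHEGERHWAN
QEWRPWLRPFSSCAVIRYMSHNEVELLMDPCPGAPTDPQCCCTDVDPVLDKPIEQCSDCH
KISYHWWHI
>gene_0008 taxon=self
DILMRRWATYHVHICSMFFVFGMIYESQYIHTIVCRCNQSEPWMSWAPEIGYTSMMFNKN
AFLCRICWSSAWFVINIDRFPTYHAVKYHNKNMNKLFDWPNQYVQWLINEELKARRDCQQ
ALVDWCCSWEGADDSKLHRAWCDMIDASGRHCWA
>gene_0009 taxon=self
WHEYHPLEYRLTGNMRYESNGVKNNDPTNNYQDYYQHGFQERTMFPSCQSHESKYSHGPM
DPTGAETQVAMQGYSIFTMYSRPQNSELICMCYFRMMDFERAVFLNCDQVYYCFIDQMWD
EHCCGPMVIGSQRYSHCDRCPHVSQCFENGHQWQIAM
>gene_0010 taxon=self
ADWYNYWIHNLRAKNKYQAISSKWLKLGCPMHTDFGMNIMGYMNSVKHHIDVVKDYSEGI
VSMDSEEAEIWQNFQDNPMQKGHMMTPEALTWHDGYALLPRPVFYTMVMSPNVNAYSFDN
SFGTTCREDENTEQPYNNCNGWHQWHADTLVSQLYHTCFLANMQHCWKYIMQFPSVRGSC
CPCLWICWQSTDQVCSQT
>gene_0011 taxon=self
LITEPKCKVDNVITCMMRHPMSGHTITHISEPKDWAYQPVEGLDEYAMIDGPQWQKCEID
PLHLIEYTIPFRHFQETHLGMSKQDPWMKCILAHNCPHHWNGGYMNSMMMLKWFGIFYVY
ATCCLWVDWNQAKENYFVKSMGKRNIHMVRNGEGNHPDDKPASFYVEIHFCYIPYRNNVY
H
>gene_0012 taxon=self
DDLMRGWPFYQVMICSMFFVFEMIYESQYPHTIVERNNQAEPWTSFAPEIGYTLMPFNKN
AFLCRPCWSSAWVVINIDRFPTYHAVKYHKKNPNKFFMWPYQGVQFLISWELVLRRVCQR
AIVDWCCSWIGTDASKLHRAWCDMHQAMGRHCWH
>gene_0013 taxon=self
DILMMFWFTYHVCACSLFFVFNMIYGVLYICTIVERNNQAEPWMSFAPEIGYTPMPFQKN
AFLCRICWSSAWVVANIDYFPTYHKVKYHNKNPNNLVDWPYQYVQTLIHPELVARRVWQL
AIVHYDRSVMGADASKLHRCWCDMHDAMSRHCHA
>gene_0014 taxon=self
GITEEWCKVDDVITCFMRYPMSGCGITHISETKDWAWQPVIGLFEYAMIDGWQWQKCEID
QVHLTCYTIVFRHFIEMYLGLSKNDWWMKCILAHWQPHHWNGGYMNSMMMLKWFDNFYVY
APCCLFVDDNQAKPNYFVKSMGRRNKHMPRNGENNHPDDKTASFYVFIHNLYIPYRGNVY
H
>gene_0015 taxon=self
DQSDCYVTHWPINMTPRWKCREQKAKKVYESIVNQFASRECETHICTMMEQLDEQWFEPE
LIGNNNRPPSMLSMATCHCHSLAIAHPTGYWYCGFCKNTWRFVPPNHWVWDREFQQPPDI
GEDICMTHWVNHCPTFEHVASWRLDNFRDHLDMHQQAWCFIPMDRDAYLDFGNTGLSAHC
PPMH
>gene_0016 taxon=self
GYKVFQGWIWNQDPGVNHLSTHCIRNEKDKFHERSVLWPKTKGNYPYHTARTYFIPMPFV
YVSCHEDDQFLEFQDYICQIYGGPFSPKVGEESTNDPNPQFWQAWNKWANLTNFLHTFFG
EWDDDMIGTINVGDNQCAIYMIMERWQVQGRRDGPTLNLFMAEMHGQWDKGRYYYKDSNW
EFA
>gene_0017 taxon=self
CDFRHCSETILKFQGVQRMCYEAIKPWFEIWLVPGKIERGSCMKIFVQMRNCTDTECPCT
PANCWDESDNDSKMSKNCYWNRACTFMVAEGHGEQNRNCQEMCEHKWKYCAQVNVIFSYY
FPPDIEEGMNWTANKYLYQPYPSAKKPQDNQGRNEIMWDPMH
>gene_0018 taxon=self
CDFGHCSETILKFQVVQRMCYEAIVPWWEIWLNYGKIERGSRMKNFVQMCNCTDAECPKT
VANCWMEAENDSHMDKNCQWNRASTFMVAEGHGEQNRNCVDMQEVREKYFAQVNWICSAY
VPKDIEDGMNWTRNSYLYFPYPSAKKCQDNQGRFLIMWDPFN
>gene_0019 taxon=self
CDFGHCSETIVKFQVVQRMCYEYIVPWWTIWLYYGKIERVSCMSNFVQMRNCTDTECPKT
VAWQPMHADNDYHMDKNCQWNRAMTNMAAQGHGKQTPNCVEMCEHKEKYCAQVFWIFEAY
VPTDIEKGMNWTRQSYLYFPYPSAKKCQDNQGRNKIMWDPFH
>gene_0020 taxon=self
HRAQEHVHNDPIVQWFHNFLTFKWYMNDVVTESCDEPHQGDWNWHIQRHTYEECHDMPRH
GPNEDHYRMDAAKERCYQKNLSFSNSHPVCFQEPHQHDYWVNPYDSFIDREAAQNWREMC
GGNGSANENHLHECSMKFETIQSPWLVQYQYAPHKEGVAAHSASNTSYALGSRKNANYTW
MNVPWFW
>gene_0021 taxon=self
NDFGHCMETILKLQVWQRMCYEAIVPYWKIWLNYGKIERVSCMKNFVYMRNCTDTECPCT
VTNCWMESDNDSHMDKCCQWNRASTFMVAEGLIEQNRNCSEMCDFKEKYCAQGNWIFSAY
VSTDIEDGMNWTRNSYLYFPCPSAYLCHDNQGRNHTVWDVFH
>gene_0022 taxon=self
DRNQAPFCRMACFTVVVASFKKRFPDSMSLTGFNDSGWELKYYNIMPTRPQIEAWYVECD
NDNLSWGCSPLGAKAGCIYKRHRLTNSFRCSLLAHAFCENTSPPWWDMCKAWQGMNMSKL
QIAGFKCLKRMNHVSFQRRFTPWKGRPGPDHWSPIYLQGRAMTYSYNY
>gene_0023 taxon=self
SIFGRTSETILNFQVVQRMCYMAIVPWWEIWLNYGQIERGSGMKNFVQMRNCYDTDCPKT
VANKWMTADNDSVHDCNCLQNRASTGMVHEGHGEQNRNCVLMMEEKEKYCAQVPMIDSAY
VPTFIEDGMHWTRNSYLSFPYPSAKKCMDNQGVNKILWDPFH
>gene_0024 taxon=self
PAHDMKLIEVFIHNQSMTKRQCYTQTEGMYFEFTHIRVCRDVDGGMKCSGRRHAWLGIMI
HADAYIAKEYRGRRQTTYECVQAALNWMCGVKMRLYGAFGNQGQGGYALDQKIRPLRHEW
PDHPSYMWPWVLNWGNCVTRQDTRYRDHLWITHQLSQWYSINIIAWGFYKHYYG
>gene_0025 taxon=self
GNLCWHRMPFVPDEKEYYTHQQTERKFNCETFCKHKIPKNPGSDLIDQKEQFDGWHLGGW
YRYYKYGRATVVYIKTHKMMLCLPSVTWFRDKCEALPWQDGDSQKDRGDKPSKYMGIGYT
PLAHWACECFACPDCRMIFWVNYPDCREKPQPGVHIRTMVNHEEDQSLIQQGVYSDRIYH
HYG
>gene_0026 taxon=self
DGTWDSEELQEQSKHYHLERWQHIGDPLQNCEFFQVTSHVKRGGWFWQVCNYNLVAWQGH
IWDRQAVLGHRFWSSRYLLGCFCCLAGVMGQVVLTEYVWCMNGCLFIAAITFPPDCYNLY
GSHPQQHTATWQTEIRDLPKSTRLESNLLGKRVMENLHWMDCKFYAFDWHWDTWSNPKAP
KNQVQRKSWFCCGDIVH
>gene_0027 taxon=self
MLFMKRSIWMMSDTGPVFSCCDCVFRFAGGFHMFYADRDSFWAENAKQMIFIIEFQVWIR
EMFIERTWWFMSLHDENMDERRALNPDRYYAYHSMDIVDETMSNPIMDETWMAPRGYMCI
IMHNYEDHNNMWLLICNKPVMEYQDKGSNWRGASRLL
>gene_0028 taxon=self
EFLLQAFFKIYRQRFQWKFWPNNTKLHWASQANRMNYYQPWERHMWCTNTHSAMQPTWNC
AAFWQQMCSVRLPNCMQFHSHNMMMWHSYQCYNLWRYCDKKAYDRDCWHCICEFAIEKHC
KYFKDYYAIDRHFNWWCPACSFLRMDNVWKSLEKYYLEMADTKGHMDVFTMHHCHDIKCW
CFPAHMHAGV
>gene_0029 taxon=self
AKAQCYPERGVHRHFWCTAKTMSSAIGKRAEQVMQIFEQMCICDNHIAIPKHRYKSYMWK
KIGCHRQWQWSHFSLSTFRTSLLWPWTSIWIVYSMMLFQNKQANYQWHETHKVICELCIP
AGFRFNQHCCYGYYQNQEVKEESFPFMRRNAWMQQYWDPDHVPYMYWPAGPWQMKRFDPL
CHFYEAQEMMERI
>gene_0030 taxon=self
WGCTCGGARTSCEPKIAVKLWCDWDTPEIWDYGCENSHPTQRKPFDGLSDMPWGSGENKV
KNYYFTRTQYAKPDFAQKDKVTSTIDQCGRSQHNVLNQMDFNVNLPCDLIWMWPHPTWYW
NGIFLHDYTKGGIERMFHWLEFPVHLTVIKWGLTIYMYVIQCFSCLCMNQKHIRCLNFWT
WIQKMDNKDW
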