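>Bacteria_001 taxon=tax_Bacteria
EQSDCYGTHWPINMTPLWKCREQKAAKVYEMIVNQFASREGSTHICTMMEQLDEQWFEPE
LIGNNNRPPNMLSMQTCHCHSLAIAHPTGYWLCGFCKNTWRFVHPNHWVWDREFQQPPDC
GLLICMPHWVNHCPTFEHVLSWRLDNFRDHLDMSIHAWCYIPMDRDAIPDFGNTNLSAVC
PPMH
>Bacteria_002 taxon=tax_Bacteria
AHEYHPGQYRLTGNMRYESNGYKNNDYKNNYQDYYFGFFQERTMFPSCQSHESKYFHGPM
DPTGAEVQVAMQGQSIFTMYSRPQNSPLICMCYFRMMDFERAVFLNCTWVYYYFIRQMWD
EQCCGPMVIGSQRDSYCQRCQHVWDYKENGHQDQIGM
>Bacteria_003 taxon=tax_Bacteria
VECVSILRARFFFPRGCRTWCIIRRVRHGIITEIVHLLNATSIHFGCHFKCFGMEWEGRC
NPYRLLYAQAQCMNTYPYHMFLASYMFQIVHMCWPHHSEIWVRMRQSNWHCHEGEKHNAN
QEWRPWWRPFSSCAVIWYMWHFYMELLGNPCPGAPPDPQPCVTRVQPVLDKPIEQNSDCH
KISYHWWHK
>Bacteria_004 taxon=tax_Bacteria
IGWYNYWRHNLRSKNKYQAIDSKWCKLTCPMHTDFGMNIMGYMNSAKHEIDVVKVYSEGI
VSMDSEDAEISQNFQDNPMQKGHMPTPGALTWHDGYAFLPRLVFYTMVMTPNVNAYSFDN
SFGLTCREDENTEQPYNNCNGWHQWHAAVLVSQLYHFEFLANMQHCWKYIMQFPSVRGSI
NPFLWICWQSTHQVCSQT
>Bacteria_005 taxon=tax_Bacteria
DILMRRWATYHVMICSMFFVFEMIYESQYIHTIVERNNQAEPWMSFAPEIGYTPMPFNKN
AFLCRICWSSAWVVINIDRFPTYHAVKYHNKNPNKLFDWPYQYVQCLINWELVARRVCQR
AIVDWCCSWMGADASKLHRAWCDMHDAMGRHCWA
>Bacteria_006 taxon=tax_Bacteria
GITEPKCKVDNVITCFMRYPMSGHGITHISETKDWAWQPVEGLFEYAMIDGNQWQKCEID
QVHLTFYTIVFRHFIEMHLGMSKNDWWMKCILAHWQPHHWNGGYMNSMMMLKWFGIFYVY
APCCLFVDWNQAKPNYFVKSMGFRNKHMPRNGENNHPDDKPASFYVFIHNCYIPYRGNVY
H
>CPR_001 taxon=tax_CPR
HRAQEHVHNDPIVQWFHNILTHKWYMPIVITISCDEHHQGIWNWHIQRHTYSECHDMPRH
GPNEDPYRMFTAKERDYQKNLSFHNSHPVCFQEPHQHDYWVNPYDSFIDREAAQNEREMC
SGNGSANEPHLHECSMKFETIQNPWLVQYQYAPHKEGVAAHSPSNCSYALGSRKNANYTW
MNVPFFY
>CPR_002 taxon=tax_CPR
CDFGHCSETILKFQVVQRMCYEAIVPWWEIWLNYGKIERGSCMKNFVQMRNCTDTECPKT
VANCWMEADNDSHMDKNCQWNRASTFMVAEGHGEQNRNCVEMCEHKEKYCAQVNWIFSAY
VPTDIEDGMNWTRNSYLYFPYPSAKKCQDNQGRNKIMWDPFH
>CPR_003 taxon=tax_CPR
DRNFAPFCRYACFTVVVASFKKRNPDSMSLKDNNDSFWELKYYNITPTRPQIEAVCVECD
NDNLFGGCSPLGAKAGCIYKRHCLTNSFRTSLLIHAPCENYSPPWWDMCKAWTGMNMSKL
EVAGFKCLKRFNHTSFQRRFWPWKGRPGNDHWSPIYLQGAAMDMSYNY
>CPR_004 taxon=tax_CPR
VYTTDSNGYLWQNECFMLQRHRARTFSFWEGPLEHPMQTGPVPAICQKHKGTGMIQWPWA
DMQIANFSNCDRQDLILQTQTKQVKMVHFCAHTGSYMYSRVWIMIFVRYVPAWPHDDYTC
MIMYMVCWTCCHSAASEGTMPQEFMLGPNMVWHKKREGCNPCQEPNGKCCRIAR
>CPR_005 taxon=tax_CPR
GYKVFQGWIWNQDPGVWHLSTHCIRNDKDKFHEGCVLWPKTKGNYDYHTARTYFIPMIFV
YVSCHEDDYFLTFVSYICQLYGGPFSPKVGEESTNDHNPQFWQAWNKWANLTNFAHTFFM
EWDDDMIGTINVGDIQIAIYMIMFRWQVQGRRDGPTLNLFFQEMHGQWDKGRYYHKDSNW
EFA
>CPR_006 taxon=tax_CPR
PAHDMKLIEVFIHPQSMTKIQCYTQTEGMYFEFTHIRVCRDVDGGMKCSGRMHAWLGIMI
SNDALIAKEYRDRLQTTGECFQAALNWKCGPKMRLYGAYGNQGQGGYALDKKIQPLRDEW
PDFPSYMWKWVLNMGNCVWRQDTRYRDHDWITHQYSQWTSINIIAQGFYKKYYG
>Archaea_001 taxon=tax_Archaea
YILSAPAIEYNWLCLDESLKCKLPEHKCSICMYHAYGWEMGLWDMVLCRFYPYLYFHNKM
PAGKGRHLHMGLINVGRMINQWCGKAVPHELVMKGTYVHWDVAKQDCYNHASMYYEIVML
VGEGWCWTKCTTEIASAAPEVQVDFQSKCTK
>Archaea_002 taxon=tax_Archaea
WGCTGGGARTSCEPLIAVKLWVLWDTPEIEDYGCLNSHATLRIVFDGLSDMFWGSGENKG
KNVYHTRTQYHKPNFARHDKVTSTIDQTGRSQHNVPFQMDFNVNLPCDLIWMWRKPTYYW
NIIFLHKYTKGGIERMFHWLEKPVTLTGIFWFLTIYMYVIQCFSCLCMNQKTIRCLNFKT
YIQKMDNKDW
>Archaea_003 taxon=tax_Archaea
CHEGRRLVYDMHFNDWVCGIAPYYHCVQDFRNNLTKVCTFDEFMWIVFETPDEGGHKICC
YVMWKVQMVAVPECYISHQEPVYLETQCEPKYDEYIGMKWQTMEWWPWLPMAKPYQSTTY
QRQMARKHADVTASGHYLMCKYARYNALSWMRGQLMCTEMAKFEALIDFLHVFTILALYC
MEVNQAYGGCM
>Archaea_004 taxon=tax_Archaea
HHIKDQHKCRLHNQLQVHVCTSHDAPCEQADVHNTMIIEHWYFSDWPMSMVLESQERGKR
WQENCMEASPHSQSQQSDMTKNVEWMGIRKHNMLPPHPAMASYICHEDMCQWLPSPVGPR
DGQIWLSFAAPFEHIQGLHCCEQGHENNCTDLTDRKQFLVRWDW
>Archaea_005 taxon=tax_Archaea
AKAECYPERGVHRHFYCTAKTMDSAIGKRAVQIMQIFEQMCICGNHIAIPKHGYKSYMWK
KIGCHRIWNWSHFSLSTFRTSLLIVWTSIWIRYSMMLFQNKQANYQVHETSKVICEICIP
AGFRFNQHCCYGYYPMQEVKEESFQFMRREAWMQQYWDPDHVPYMYWPAGPWQMKRFDPL
DHFYEAQEMMERK
>Archaea_006 taxon=tax_Archaea
FLWAIQRLTCETYILSMSHNMIHPCKHYMVKGDLAQGVQDQLGFGLFTATNATSSYAVFC
LVNSQHMGHQKFATEQYAFSTFDLISKLARSKRFWSYFCSDRCWDKKIRMDEPRPAKYFP
HRIQVPQCSYISEMQCQGNYFRPEWHCYTHNLANFTQANMFVMGPYVFALNGTKQDVSHD
VQPVP
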