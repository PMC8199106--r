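>rep_fam01
TLFQSTRCQLIMKLQSILVNREFGRYWMSARGDIFHYVRNNCDQEAGAYHFRLNLGAAYW
IYCYITIAKKVHPYEDGYKCRQENEVEEVEEALVNHNAVAHDHMSFVFHMRVTNSGFHLI
E
>rep_fam02
IAQNGADNEILWATCCGGRVAHIHRCRCVLIFPPRCRDTVERMNEHNVDLMHPNLGARFL
HAHWYDEHYYNAQNNCAILLHMPVFPFIAMKMCLDSMKLMFQANRWIYIGVDHCQKEGRG
HYSRNTCRCPPSGNHQDSKKFKPGGKWVRPNIRPWWSN
>rep_fam03
IWGLEHEMMSKQTDYAPRPQHQNAADVDGNDVCWRTMEQAAGWFQMTDMAGHALHGMKWG
HASQWCHWDVYDTDQHAGWRQRMPCEDFPETTGHLCEHSQLCNPEPSQFYPRDFSKSPQS
LASD
>rep_fam04
VITYWTYWSLKVVQFFIMAWIWEKGQAANSGDPIRPTKPFTIIIINIRQHCPMYNTSCGF
ITAETLFDMAGMARGKIWCQKFDKGYVYFLVQRTWVREPPANTGCRYRAWPHLCICRNVE
DEIDHWCKSQNGTMAYLHIIEWYELACENPHRADDDVHDSHVDEKRMATPKVNMTLGTAY
>rep_fam05
ELTGNWRVTQYQEWPRVQQDGQGTVLAVNASWLKWTVHFIYSSRAGQIVASRSHTTRPKT
YHKDRLHIGATPDYYPTNSHPGAPALYTYSLEVMEVGENAWRTNTKETAHEACDWYSMCI
SRQPQMK
>rep_fam06
SGICLKYGSEWCMLAFEMSLWGDHAMEIYWPSSGIFNSMKQFGWNGGQWTHYCYMCMAFH
LPYTINVLVVNQQCEKYRQPREEGQWAETTGMPISDWPMNEGWRVTAPMWPTNSQWHFYA
GKKRIGG
>rep_fam07
WVDWFTDIANTCEADDPSWTCQLAIDRAMAKMRQQHMCQGQCDLEIEGMRTWDSEYCMQK
FTSVIVRVYRNPKYARQAPIFFCSCAFFEQLVREVCSRLTSFEGVNHFVWWHGQLKIPGE
VVKIFAGDCVPCSKNQTQLAGHTMSEKQVVMYVFCIKFSHKGVNVPHQHRNESSSRH
>rep_fam08
QQKQDQDNHEFAVCGHMNQMRLPNGDMKDQWCYMICKNCMVRFQEHQWNHMAWTHCNSTE
MFHYAHHKDFFHQVTFVDEPQNDDVTSGHVTWELGWEFPAEQMSQQQIRDYWYFINKISK
LCAEMMHWNKQANQPMAEHGHICKII
>rep_fam09
VMDAFAYVIRMCMKGGSKMWTKAWAKEKEIDDYNLDHMCMNMWAYGVTPYWESIHSDCAC
FCWEMLRAHSTARMPNPVTDGTVVWYNDCWDCTHFPHGAWPTHCIIFDSLKNEMGPRTLT
HFDEWFEATQKSGPSFDIHLNHRWHCHFCFCKCHQPHMSDGCGGVPSGFMLSEDKQNVS
>rep_fam10
NGDTFFLKQKVCFTSKVKDPKPVTVTACWSEWRYLPARINGTSRGEIGTIDLVKALASNW
QYGGWNIMWSCWENVLANKCIKQHDPDDELIYFRLYMVEVWRENMDWAICATYDLMTMHI
WIMQYIWFYWYNMPELDQHVVFTIT
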