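>sp|SYN0001|SYN0001_SYN GN=WNTX1
WDTQTWNNTHLPWDQTFWFVVYVGYELFTWESPFEPANVLLTHSVTRGTYYRTAVSHLLN
FMTCAINAVNQHYQCARGVVPSCLCA
>sp|SYN0002|SYN0002_SYN GN=WNTX2
NACQVQQFRPAAYLENRYFENYTTTADCLKYESWDPQPEPVWPRYSWDVSDCFAEGQNYQ
KWHYVDWWLQASDCQEKNNIITDRLWCSMVCAEAKDLQYFCCPDPCIEQNCSFNSSTPIW
CNRQIGGCVIEQPTPLTWSHTTPWDVITGHEDALWCIQRI
>sp|SYN0003|SYN0003_SYN GN=WNTX3
ARMPGQCVGVYHQMSVMLHFGNMPYVLLGHSLCLTYEGPLPQTWALCPTSRPLGFYDQLD
AMMRDMRRFFSMQHQTFFAINITAEWHAPHYVTMLCQLHYWPTIRSHCNALEIIPMDWKK
MYTCPVMKAPMFCCWFHIHSL
>sp|SYN0004|SYN0004_SYN GN=TFAC1
GFYGWPHIWFFGENQWYCCHWYHHDVSCWMDISPDWRWKDFMVSKFSKSPADTHVFSQQG
TEEMIVGLCEPTGRPKIDHWCLDPRSYKDWSKQWICIMEFYSECTEMQNSKVCRTSRVYK
IDEFEDHAIMGHWVWYFETSSHGGIGKHMRYVHPDNV
>sp|SYN0005|SYN0005_SYN GN=TFAC2
PVKDGSAQDTFWPRKNAAYMKDVSVCQYGLPTPVWSMYNCHLWTPVRKMPWGWMSQACNQ
MAYIPLTPMDTLVMGSSYMNKRWTWFDT
>sp|SYN0006|SYN0006_SYN GN=KINB1
RWTDNNQPHKIMWHSNGNGCSKTNIEVTRNIMPGAINAQETREAKHCMDAVSGDPVASDH
DQAQHLKFKHAQQVPATENLRSHWKWKAPQPWDELRMIHEMVV
>sp|SYN0007|SYN0007_SYN GN=KINB2
VGAERQGLPHTCSDTFVFKCLAAKRKNSPDPLFQERFLVALGQRGSFGSMFHCIYNKSEY
DLRRLGVVWLHMISDSAKPRKWEDRRNMDLSDDHTIVDQTWYEKQAFWQAAMCLFSI
>sp|SYN0008|SYN0008_SYN GN=RASL1
KQCEQICPNIIRNTLFEADISTVSEIFFPTLHPTPSLEMNLHAPQPDRTKEDALDQCEIL
IFCSPGAAEHMRDSQGTCTRDDRPHMPFNAF
>sp|SYN0009|SYN0009_SYN GN=RASL2
DYATNPFAVDNACNLQGLCCHMMMPFFQMFCDRVVWCDAGMCHFALYWLQMLWYVWWGSH
FTPFNHDQMFKFVRMVDSPSSDWCNGYNHHMQGCSAHMAL
>sp|SYN0010|SYN0010_SYN GN=MEMB1
DFCVFCIYRFSHPGASIYRWGWIKCMDWNQKFYHMEACEPPSPPGDNQSRSNNGIFPTTP
AQWREMENFFLGWLHMSEVHS
>sp|SYN0011|SYN0011_SYN GN=MEMB2
TATFDVRTWCFIPLSPDGDNDVKQLFVMYRTGPPRPRDRRRHWGYNTTSPRVDEQWVPSH
WNDLQAMGAGSKKYGFYQAYAEGEMMDWMEPNAW
>sp|SYN0012|SYN0012_SYN GN=CYTO1
MHRPSNNHGSIPRERYWAHEMKVKDITIHVYHPHWLRFWMILHSNEQWEQRLQQQEWLDF
VEVHRFFYITPPSPYCSSAITMRPRCWWWCPPTPDEDNVDAEAGHDWFMYAMVLHQWAKL
RDEDQINKTMDVGNLLQHSARPRDLMPHYMYPQNVNDFIS
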