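# SYNTHETIC reference table: Asgard CdvB homologs (two clades per genome).
# Constructed (not transcribed): CdvBa1 rows carry a proline-free N-terminal
# helix; CdvBa2 rows a proline-broken sub-threshold helix and a planted
# MIM2_total motif at 198-207. The domains column lists externally annotated
# domains as type:start:end triples.
protein_id	organism	clade	seq	ss	domains
LK_CdvBa1	Lokiarchaeum sp. GC14_75	CdvBa1	AASDRITKIQTCFTKKQSDVCGFCNMNGCGTWAFSMCEYNKIARVACHSIFEQYGQWYEEFLANEIYLGLIYHNFSTGNDFYKKQGLDTNTRHMYMDWRNILFQLESAKDNWMAADKWIICWTAWEVHCALKFQNQTNLGACIRNVAVMSFFYALWHYDQMDATRTELQSDAGSQAANLEFILGIVAVVHSKQDYGYMQWCLAWSKRYAQRVKHNICKDM	CCHHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:30:190;MIM1:200:215
LK_CdvBa2	Lokiarchaeum sp. GC14_75	CdvBa2	DWWILYVSCPRDEDIYGDKQAVMFSERYCFGCIAINFGQWSASYKRCKVDSDQVLRINRYEAQTKRLYICSQWDDLISRCGGLRFGDRDWYCSHAAFKSKSVAYQKHRIDEAHSHDRNIYLGYYTAIEWVWGNKVGFGQFYQCVQLHNWFYNFMTHYNSGFQMIVTTNLNRGSTLTRCIYANSTRVHHWGKYDVHQRWPKFPRRPVPRTQIATNGCFLNF	CCHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:25:185
PS_CdvBa1	Candidatus Prometheoarchaeum syntrophicum	CdvBa1	DHGDQYMTIVAKACETQLTHHKSSLITGDHHAHAGWTIGNQIEEKGVCLLVVIWRIRMFAHERGRDEVKASRAAYTAVHAEKSMHRNWFEKIMWIECMCIYFYFVQCNCLQMHYFIECTCSLSAWQRTQRHYFTHVHGMWIKQQNEQKEDHYAHFWHMEGQLCVNTEIYYMHWSDSSKGQIFGCREMDITVGACRDSYQALEYSSHIFNFRNCLFSAIGF	CCHHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:30:190;MIM1:200:215
PS_CdvBa2	Candidatus Prometheoarchaeum syntrophicum	CdvBa2	SQCGQICMAPYYRYFTFWGFRLTFCMNVLNRSQDAEMGQMHQCYCHMWLCLSSEVSVCDRQRKTKCIWVWFKSNAMNHNEEMTFRFVFRQNEDCNATHHQDYLFKMTVELQHKEGIVENASTYLGNYSTGRGLHYITWANYQKWTLIRGDGMRKLQLRKHFLRWVSHICFLMATESHTVTFHSNAKIIKRYFDECMKMPEFPKEPWPHCANVSGTDCVLF	CCHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:25:185
OD_CdvBa1	Candidatus Odinarchaeota archaeon LCB_4	CdvBa1	CEYEHCLCDVKRHYFSYESKEMYEKLMEGENFWGQWIRLGWQVGKTITQNFDVLDLMNVYKTCMRCSKIMVFVNMKRNDKEDYSEIYDEQGKIIKNDVGLAIYCLNVCRNDIYNWFRERSWKSDKFQHSQSLDHSSIATEHFLRGMVKHQVYWGYMGLQYMGDVIFVAYFCFNFSSLCAYWYRKIWVALLNTCQACHRWVAAFCQVVWYNIGIGWYYFHN	CCHHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:30:190;MIM1:200:215
OD_CdvBa2	Candidatus Odinarchaeota archaeon LCB_4	CdvBa2	VQETWDWERPNMFTVYWRLKSKFKCWWKRKMWASTYNIMCEMISQKHENEYFCIIWVYSVQWFIFKNVSGHHKTIFLYMGDMAHLSKTYRIAHCNIYEDIWAADGAWRKGHSRAIQMNWHVIVVFGDRNYFTTYWEIIRHVIADQINLNLWASWSREYDIFNVMRILQFVDELHACYVRVVMECFGEDFQGHENTMQPPEGPERPAPLHWCSDDAETTWV	CCHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:25:185
HD_CdvBa1	Candidatus Heimdallarchaeota archaeon	CdvBa1	WSKMWHAKACWKHLITTLMHHYMWHYKSYRGSHVWITASQASVTTLLYSCECSFNMGKLGSWKNANRYRNINQVEYEADQKMGMLNITTYEVGGLGWVSSNYQAGQDRNWSMELMTTCLDTCGLNGFVNYFSSREVSQHVKIMVGMRGEDLNGVTKIKMMDYFVLVDFIACFGVHQMEMEAGKEAYQRRLYMADRSMYHNVAHQSCWEQMNVHCENCHKC	CCHHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:30:190;MIM1:200:215
HD_CdvBa2	Candidatus Heimdallarchaeota archaeon	CdvBa2	QRKDTRVLQPDQFTVSKYLFCFAMMIYAGNSETVTMQIEKQCGNKEGVINGFIKRIRQSERLCDTGWRFTWRSDIVDKAMVTRDFCESNMVRIKDEQRHKMWLMVTCNMIQRNVCTDLKMWCLDHQINCSMQYTMVGQQYVKWMCGLVCSMEEQISEGYWDFEHLNNVKAKGMTVCGTKTTSITTVATYELERTWSYWPKWPDDPFPHVTTDLGVCAKDH	CCHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:25:185
TO_CdvBa1	Candidatus Thorarchaeota archaeon OWC	CdvBa1	FSWYAWIVDLYQVVYWWFTMHMCFYQWSYFHARNFMNLWLCFNMGDFVFCRLHFIVCWVKHDIMFMSQQFFTAYRQSRLLVSTTIVASGNHQKHCHSVFQFLYQWFSMRSVLFLWMRIFQADASDHNCEDNDQEKIGEMLYSYQSKQKDMSWHDFEENNNSEEEFAKTRRFTGRYKHVYASECWKTGFSEYGFLCNVDDVYLKIEDEMHTVQAQACSWVF	CCHHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:30:190;MIM1:200:215
TO_CdvBa2	Candidatus Thorarchaeota archaeon OWC	CdvBa2	QRLTHITDQPNVNGDWNEQKSGSRFQKNADCICWDFFCLYDLGKDRRGKQMRDNWRETGSCLSWHAMMHKMTTQMKDQRQNAMYAGMRDRFIYWMFFRIARTSCINKLMCTWLLYREGYWTIVDQMVMDMFDQIMGSGITRVGGFGVEEIFIDKYEFWDGHKSQRYNKDGYMHVNIMYGKCSSHNISDYFIFKWAQKPPDFPEKPPPIAHSCGSEVIEKH	CCHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:25:185
TA_CdvBa1	Candidatus Thorarchaeota archaeon AB_25	CdvBa1	GLYSYDFNMWFFREDTRYLNVIIQDTLALLQRVSARRYKIGLYCKNVCLMWTECHKAKTADRKGFQLFLESIHGGNYDQRAWAQLMCLCMEAIRRHSNRTFVRRTQHQFHISDLWCRAHHAGGVMWKVSFVHRHCLLGLYQHFYDIDEHKMWCNHDTGNVTYLAQMRWTFFSGGGVCGAQRMQTSDRKGHFCAWIWYWIGWQDMVEDDFWEDKEANEVNE	CCHHHHHHHHHHHHHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:30:190;MIM1:200:215
TA_CdvBa2	Candidatus Thorarchaeota archaeon AB_25	CdvBa2	FLIWIWYSVPIKNWMVVQWCRWMWCMEEKHFHAYGFRCGYFQKFCMCCRLMMCAFCFRLCRDSDNMAHGDSVVVYVHMEDGKWWCNNQVQLDGLYHKKAIIGCHLATIHDIHADEVSTHHCWRSWYYQFDKADVIRHGNWWTQSNSMVGSHGRTRESEWYCNGQLKNNGHTENRRAHNIATKEYWLQVGKNRFRSQEWPRWPEEPAPFGIWQFKSTIMWA	CCHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC	Snf7:25:185
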