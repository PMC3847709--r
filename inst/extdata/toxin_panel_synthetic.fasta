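>TP_3ftx_01 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
PHPRWEHKEPRQHDPKECNGAIVCNLAIICYDASYCKLIQQYCFEFCHGDTCSNSHVCRSTCDGVCTN
>TP_3ftx_02 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
PHPRWERLEPRQHDPKECNPAIQCNLKIICYQAMYCKLIQLYCVEFCNSDNCSNSHPCRSDCDANCTN
>TP_3ftx_03 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
PHGRWERLEPRFHDQIECNGASECNLKIICYQASYCKLQQLLCFEFCNGDSCSNSHVCRSDCDGMCTN
>TP_3ftx_04 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
PRPRWSPLEPRQHDPKECNGTITCNSKIICYQASYCKLIQLYCFEFCNGDTCANSHVCRSDCDGRCNN
>TP_3ftx_05 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
RNRNKNLYDNDNRTEQVCHNKEDCGPDTPCLKVDECDRRRGFCAVPCNYGTCNTFYRCEPICHGNCYH
>TP_3ftx_06 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
RNRNKHKLDMDNRQEMVCGNKEICQPDTPCLKVGECDRPRGFCAVPCNYGTCNEFQRCAFICDGNCYH
>TP_3ftx_07 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
RNREKLWLDQDNNTEQVCGNKEDCQPDTPCLKVVECDRRRGFCAVPCNYGTCNEAYRCAPICDGNCYH
>TP_3ftx_08 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
RNRNWNKLVQDNRREQVCENKEDCQPDTPCWTVDECDRRRGFCVVPCNYVTCNEFYECAPICDGNCDH
>TP_3ftx_09 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
LFLPEDRLWIDMQQQEECIFNRNCGKNGMCVANRECMTGSLACNPLCADNGCDELGKCLKPCAKNCYG
>TP_3ftx_10 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
KFLPEDRLHIDKQRQETCIFNRNCGKNGMCNADRECMTFSIACNPMCIDLGCDHLGKCLKECNMNCYG
>TP_3ftx_11 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
LFDIQDLNLKQYIMDFGCSTEAQCPGDVNCLNFFECGKEGGTCDLECPFSRCGGKAACYMQCHRYCED
>TP_3ftx_12 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
LPDIQDENIKHFIKDFHCHTEAECGFDVNCLTPFECGKRGGTCDLECPASGCGGKAACYMQCSRYCED
>TP_3ftx_13 family=3FTx keywords=three-finger_toxin|3FTx description=Three-finger toxin, synthetic ToxProt-style ortholog
EWHNEILEDLQEDQEFKCYDITLCQQKEKCEREEQCSPQTGMCKLKCVTHLCQEYQDCITPCRIACDT
>TP_srtx_01 family=sarafotoxin keywords=sarafotoxin|endothelin description=Sarafotoxin polycistronic precursor, synthetic ortholog
MQVMVWVVWIIHKRCVSKHDCGLAMKDNVGVKQAPDEPHWMYQYHHLFNIKRCVSKHDCGLVMKDNVGVKQAPDEPFWWILWWNIQLFKRCVSKVGCGLVMSHNVGVKQAPDEP
>TP_srtx_02 family=sarafotoxin keywords=sarafotoxin|endothelin description=Sarafotoxin polycistronic precursor, synthetic ortholog
VHWFFMWYHVYMKRCDAAFTCDFEVHTKAKYDDSKDEPQMFYLWNQHLFMKRCGHGYQCGKDDNEQGVVHNGS
>TP_lipo_01 family=lipocalin keywords=lipocalin description=Venom lipocalin, synthetic ortholog
FLVQVPFREPKDHPQHPTQDNSEDLFPDEKPTKPNESTVFQRAANQRQRKETYRINDKVPNGKKEQECPGNVFPFHKLNLTLANDDDHKKQSQEGEDETQKELGRVWPDTQGTKHMGVARKKVKLIRAQGECTKHPDENYSHRHVEPDAASKMLYARQ
>TP_lipo_02 family=lipocalin keywords=lipocalin description=Venom lipocalin, synthetic ortholog
FLNQVWFREPKDPFQHPTQDNSEDLFPDQKPTKPTESTVGQRAANFRQRKFTYRINDKVPKGKKEPECEMNVWPFHKLKLTLANDDDHKKQSQEGEDETQKELYRVYPDTQGMKHMGNARYKAKLIVAQGECTKHPDEWYSHRFVESLAKSPMWGAFQ
>TP_lipo_03 family=lipocalin keywords=lipocalin description=Venom lipocalin, synthetic ortholog
FDNAVWFREPKHPLQHPPQDNSEDLFPDEKPSKPTESTVHQKKANQRQRKFTYRINDKVPKYMKEPECEGNVFEFHKFNLTTANDDDHKKDSQEWEDETQVELSRVIPDTQGTKHMGNARKKILLIVQQGECTKHPDENYSHRPVENDAKSKMIYLFQ
>TP_crisp_01 family=CRISP keywords=CRISP|cysteine-rich_secretory_protein description=Cysteine-rich secretory protein, synthetic ortholog
PRRNIFKENNNEWRFMDWSYGIGCHAWLGNVEGARCTSEVIAQLAPSCQGGTERIHFLFCQKGSFLAKTAGCKDTKQGKILKQCMGYRIIESRMDCVEDGRKRERDRCASQNSDSKKNKCQALAFPKHINACGSTYAGTTREECMQITSYTRRVSCMKYGQMIEVVECRTYLFFAQDQKCELVFPTGCLMAEAALCWQDE
>TP_decoy_01 family=kunitz keywords=kunitz|TFPI description=Kunitz-type protease inhibitor, synthetic decoy
FIGLGEVLGGGAVVVFQAEFCESHVEVVLEGDCAQGTTLAPTTGKPGGAEFTLLDGSD
>TP_decoy_02 family=kunitz keywords=kunitz|TFPI description=Kunitz-type protease inhibitor, synthetic decoy
IRYMGKYFGELMNDLVAYGHLAEDWLKHQRTEPTCGVAVVVEQKVHLILRINSTSICENI
>TP_decoy_03 family=PLA2 keywords=PLA2|phospholipase description=Phospholipase A2, synthetic decoy
HLQTLASSGQVAANGGEIEWTDDRVGLCQAFIREGDRKVCSRKAGQEELKPLRFNKVSGTKMAQTVMNLACCHVVLPPSNVMFVNEVYNLSGPLYRTGVAGVWSQPLQGPAFVAAKAENPYM
>TP_decoy_04 family=SVMP keywords=SVMP|metalloproteinase|disintegrin description=Snake venom metalloproteinase, synthetic decoy
AEVLSKFGILDPSHLDGSEFSFNITMSLQYYKQSWIAVPLAKLSHFRQPGEPTGTFKLKINELGGSELVACGFIGISQVNCDVAIDRFWLCGSMLDVYDLRMFTLNMPENPVLVTLTIHQSRPIASPPNDIDLLDVFVDPWALAKNRLSQFLLGLMTAVDYLVVKDGDIKHVKTKSCPNDGGGPDEMKGVIRVRFMNNPHVGICN
>TP_decoy_05 family=waprin keywords=waprin description=Waprin, synthetic decoy
KKADGPQITRCGLHHAYPACRNTNAAIYGKNIVIMKEVEFVAWMVAEFNV
>TP_decoy_06 family=lectin keywords=lectin description=C-type lectin, synthetic decoy
VTACKDMLKECITRPDFNTQLDPAKLLASRAVRYQGGGLDHTGTTFKVGWDGAAHRRNIKDASIVLPRLFIIVKKHKLRHVRCIKAIFPSALAIKEGGRADLLDEDLLDVQEEPRDCINTSKGVILVNF
>TP_decoy_07 family=lectin keywords=lectin description=C-type lectin, synthetic decoy
RCDELTRQATFSDHNGDCHDFLTKSPISKGQGEKTVKTLIQRVLVYVIIRAWQMLLCGMAISTKEKKAQQGMVHSESWQAPSSFLVEKNVRCRSFGVLKDFSPFPKERPNMCEDGLNFTPTCRPAKGDGNLRA
>TP_decoy_08 family=kallikrein keywords=kallikrein|serine_protease description=Venom kallikrein / serine protease, synthetic decoy
EFQNETNMNAWNDADFATDGEHKTSHRGVDSKKNQYDAKDGLHFQNGWKRDAKLLFFAHFDTATGHQFQIAKDKAGVAEPEKVACNSKLVKLGTAVFPNDAPPFDKVRNYFAGKVGPTLVGPILRCTYVFAVLGLMYQLKIVGHNPSEYCRYYQERRDEETLRRMFFSGELAPDELVPACKRVIATGYKVNNVCGAIYRCLNSRCTPFKLHTMFKFTGDAQIDALWSALEQS
>TP_decoy_09 family=AVIT keywords=AVIT description=AVIT venom protein, synthetic decoy
GEVLWFSSASIAVANYHGKFDIAKMETRICLAENLDKSGKLSPYLCCDFFGLPAGYLESCEEFAREMNTAELQNEKDLIKA
>TP_decoy_10 family=crotamine keywords=crotamine description=Crotamine-like myotoxin, synthetic decoy
RGTEHKLCVKVECTVLGVSFVFQKNAVEGWCELSIAIHEGAS
>TP_decoy_11 family=cystatin keywords=cystatin description=Venom cystatin, synthetic decoy
KLLAWYLVLNKLEIQPMHKRDVMYRIPIIVPHIPDSRGENREKPHAGFCQLLPWLTLAGVSQEKSSANAEIIKDRDYEYDAEDNDKPGNSQCSGTLFQAVAVKFSPRFLV
>TP_decoy_12 family=natriuretic keywords=natriuretic description=Natriuretic peptide precursor, synthetic decoy
SHHQLLLCIQRKVLAMGYSDDKIPLTSQSTALVLGDDQKTNLKNIHDIAYYGAFILRLKANFRVYQMCVRQKDCCLWWGQAVDIGVEIHADCSIKLGDVG
>TP_decoy_13 family=VNGF keywords=nerve_growth_factor|VNGF description=Venom nerve growth factor, synthetic decoy
NLVVHMKAIPDGFLNLMVSRIDSDDELLWFNLGHIDDLQIFLVFDDIRVHTYLEGGVDIVGHLSLVVILGAGQGTRRSLPVVADRFVNHSDKMLCFLDKGASEALYIKENLDQTPTEA
>TP_decoy_14 family=cholinesterase keywords=cholinesterase|choline_esterase description=Venom cholinesterase, synthetic decoy
IRSVGTFRRAYKTGSGVLMRTIQLMLEDELDVVREKIRNQDGVFLIVDMFVVTGRSVSFMWTLKVVISKSVRQCHAVTKRMLQTYDIPLCGMAGCGQTSVPQPRVWMSADIQGIEPKSGKAKCLAGEPEDPGSTELYCTQADSLFRPGHTPIYAIPILYPTLFDDEADMLDVVKDSFLGRQQKRRARALWLEGNDCESFTFKMRFGESNSASSVLLVEKSQTGFEGKYVLRASREFLHDPRVKTDFNL
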