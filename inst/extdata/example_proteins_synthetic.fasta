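>SourceBac_01 synthetic bead-on-a-string protein
DVCTMGGIPATACDSFHHFTFVDDCVWYQAWELHRRMSPWTSCYAHMQKRIVYSIDVFQA
ISHNRVFGPDRLIAHQPYQCVFSNAGKLANHVFDGKLWQLTFNIREMMLHHSQSIINIQN
HFERRDWCEWYQAWMLHRRMSYWTSCYAHDQKQIVWSIHVFQWISHNRAFGMDSMTIEQP
MQCKQSNAPYRLNHVFDGGLKQFYKKPLEAESTPPHECEREDVEWYQAWFLHRRMSFWTS
CEAHDQKQIVYSIWVFQWISHNRKFIMDRMTIEQPYQCVHSNATKPLNHVFDGKLVDENH
MMCFQVTTIWWVDL
>SourceBac_02 synthetic bead-on-a-string protein
MKIIKESDKHCPPRHFTSVFDCFIYQAWELHRRMSPWTSCYAHMQKRIVYSIDVFQAISH
NRTFGPSRGIAHQPYQCVFSNAGSRLNHVFDIKLHKIWYMWGDNHWITMLCFRHFERRDV
CEWYQAWMLHRRMSYWTSCYWHDQKQIVWSIEVFQWISHNRAFGMESMTIEQPMQCKQSN
APYRLNHVFDGGLYEAAHAPDNRHNTLCQKFPCSNSQRHFCEREDVEWYQAWFLHRPMSF
WTSCFAHDQKQIVDSIDVFQAISHNRKFGMDQMTIEQPYQCVHSNATKPLNHVFDGKLGY
ISNVAIAYTHYFGV
>SourceBac_03 synthetic bead-on-a-string protein
ENAGAHKGGRFPHPTSVDDCNWYQAWELHRWMSPWTSCYAHMQKRIVYSIDVFQAISHNR
VFGPDRGIAHQPWQCFNSNANKRLNHVFDGKLQHELEKHPYLDYHFERRDVCEWYQAWML
HFRMSYWTSCYAHDQKQIVWSIEVFQWISHNRAFRMDSMTIEQPAQPKQSNAPDRLNHVQ
DPGLWPMCCEWCNAKYPLWMSFEDDMIHFCHRADVEWYWAWFLHRRMSFWTSCFAHKQKQ
IVYSIWVFQAISHNRKFGNDRMTIEQPYQCVHSNATKPLNHVFDGKLPSNPIMVKLAEKP
SEHQTIVEPDMA
>SourceBac_04 synthetic bead-on-a-string protein
KFWSSGYAMCLAEHFGSWDDCFWYQAWELHRRMSPWTSCYAHMQKRIVYSIDVFQAISHN
RVFGPDRGIFNQPYQCVFSNHGKRLNHVFDGKLAFVMFEETFDNWDFKIRFYNRSRHFER
RDWCEWYQAWMLHRRMSYWTSCYAHDQKAIVWSIEVFQWISHLRAFGMDSMTIEQPMQCK
QSNAPYRLNHVFDGGWRDRTTSHWMTARRMVPIHFCSREDVEWYQAWFLHRRMSFWTSCW
AHDQKQIVYSIWRFQAISHNRKFGMDRMTIEQPNQCVHSNALKPLNHVFDGKLHDTEKAS
QHFRIRLCA
>SourceBac_05 synthetic bead-on-a-string protein
TMTWYAYYGHRPWGMDAAERWHFTSVDDCFWYQAWELHRRMSPWTSCYKHMQKRIVYSID
VFQIISHNRVFWPDDGIAHQPYQCVFSNAGKRLNHVCDGKLQHHRQWMGDGFMLSGPAWE
QGTKHFERRDVCEWYQAWMLHRRMSVWKSCYAHDQKQIVWSIPTFQWISHQRAFGMDSMT
IEQPMQCKQSNAPYRLNHVFDGGTHLKFLLVMYGKVWHYHEFIKMFVHWHFCEREDVEWY
QAWFLHRRMSFWTSCYAHDQKQIVYSIWVFQAISHNRKFGMDRMTIEQPYQCVHSNATKP
LNHVFDGKLLANKPNVTYD
>Organelle_01 synthetic bead-on-a-string protein
LFTAIAFCVQTYSYHFCEREDVEWYQAWFLHRRMSFWTSCFAHHQKQIVYSDWVFQSISH
NRKFGNDRPTIEQPYQCVHSNATKPLNHVFYGKLVRMMGNGEHGNGFYHFCTREDIELYQ
AWFLHWRMSFWTSCFAHDQKQIVYSIWVFQAISHNRKFDMDRMTIEQPYQCVHSNATKPL
NHVVGGKLYSYRDKKEGMHFSGYQMAWHRRMHTCEREDVEWYQAWFLHRWMSFWTSCFAH
DQKYIVYSPWHFQAISHNRKFGMLRMTIEQPVQCVHSNCSKPLNHVFDGKLCYVYRMSRC
SISERCHC
>Organelle_02 synthetic bead-on-a-string protein
RGETQKYGGNDQWLKMDDDEYMHNCTREDVKWYQAWFLHRLMSFWTSCFAHLQKGIVYSI
WVFQNISHNSKFGNDRVTIEQPYQCGHSNATKPLNHVFYGHLMTNGTHSHGMCNSFFYEE
VVKAKCHNCEREDIEWYQAWFLHRHMSFWTSCFAHDQKQIVYSWWVFQAISHNRKFDMGR
MTDEQPYQCHHSNATKPLNHVFGRKLERRVHRHNQIFGREIFTVHTCEREDTEWYQAWFL
HRRMSFWTSCFAHDQKQIVYSIWVFQAISHNRKFGMLRMTIEQPFQCCHSNCDKPENHVF
NGKLQTGSFNHFNN
>Organelle_03 synthetic bead-on-a-string protein
EIAKHYHEVNVIWRNFPNYHFCEREDVEWYQAWFLHRRMSAWTACFAHHQKQIVYSIWVF
QSISHNRKFGNDRTTIEQPYQCVHSNATKPLNHVFYGKLVMMHWQGIICRTHFCQRYDIE
WYQAWFLHRRMSFWTSCFAHDQKQIVYSHWVFQAISHNRKFLMERMTIQQPYQCVHSNAT
KPLNHVFGGKLWQQMICGHMVQLETHTCEYEDQEWYQAWFLHRRMSFWTSCFAHDQKQIV
YSIWYFQAISHNRKFGMLRMTIEQPFQCVKSNCDKPLNHVFDGKLPAYNPLYKFVTS
>Organelle_04 synthetic bead-on-a-string protein
YLWFKTLKIHNYIFMLMTYGDTHFCERERVEWYQLWFLHRRMSFWTSCFAHPQKQIVYSI
WVFQSISHNRKFENDRDTIEQPEQCVHSNATKPHNHVFYGKLSEPDHGINVKMTTGNTDC
LHFCEREDIHWYQAWFLHSRMSFWTSCFAHDQKQIVYSIVVFQAISHERKFDMDRMTIEQ
PYQPVHSNAPKPLNHVFGDKLMAREAYTVGSYPHVWRLTREVFNHTCEREDVEWYQAWFL
HRRMSFWTSCFAHDQKQIVYSIWVFAAISHNRKFGMLRMTIEQPFQCVFSNCDCPLNHVF
DGKLTQELLCASIKPSAFAPGM
>Organelle_05 synthetic bead-on-a-string protein
VSHSPDDMPHHFCEREDVEWYQAWFLHRRMSFITSCFAHHQKQIVYSVWVFQSISHNRKF
GNDRPTTDQPYQCVHSNATKPLNHVFYGLLFGRGTMGMKLIWQAQHDRGWVKPSHFCERE
DIEWYWAWFLHRRMSFWTSCFAHDQKQIVYSIWVFQAISHNRKFDMDRMTIEQPYQCVHS
NATKPLNHVFGGNLPPHQEFCCNEQFAHTKEREDTEWYQAWFLHRRMSEWTSCFAHDQKQ
IVYSIWVFQAISHNRKFGGLRMEHEQPFQCVRSNCDLPLNHVFHGKLNWNEDNSTEQNQ
>OtherBac_01 synthetic bead-on-a-string protein
YTICCLHTAKHIWRNDVCFWYYKWLLHRRTSMMGSCFAHDAKGIVWSSHRFQKISHCEMF
GRVLQAIMWPTQMSGSNAPHQGNHVPDPDDNHVECEDSPFGRHIARRDNNFPYNYWLLHR
RTSMFRSCFAHDLKWIVGSSQAFADISHCYCFGRTRMALMNPYQCSFSNAPHVGNHVYDD
ADMKDCPDRVAIERDSPCIITSLIICAHIKYRDKCFVYYKWLLHIRISPMFVCKAHTKKQ
IVQSSHRFQKISHCTGFGRYRAGFMWPPQCSFSNLPHQHNHVPDSADPCFEWPIFHRTVI
PCYKQS
>OtherBac_02 synthetic bead-on-a-string protein
PVHSWMKKDLVGGDHVPDHKWLMHIRRNKVCFWYYKWLLHRRTSMMTSCFAHDAKGIVWS
SHRFQKISHCYMFGRILQAIMWPTQCSGSNAPHQGNHVPDPDDGGLYCFIANPNWPHWCC
HIARRDLCFPYYYWLLHRPTSMSLSCFAHDVKWIVLSSIRFADISHCYCFGRTRMMLFNP
YQSSFSNAPHVGNHVYDSADYPIIHCYIPTMMDHTRYLPMMRVEHIAYRDKCFKYYKWLL
HICPSPMFSCKAHTKKQIVWSSHRFQKISHCTGFGSYRAGFMWPPQCSFSNAPHQHNHVM
DSADFEVCLWCADICTAA
>OtherBac_03 synthetic bead-on-a-string protein
PCKHTDRAYQHKNLKGHACHIDGNDVCFWYYKWLLHRRTSMMGSCFAHDAKGIVWSSHRF
QKISHCCMFGRILQPIMWPAQTSGSNFPHQCNHVPDPDEFEYNKLTMHASHIARRDYCFP
YYYWLLHRRTSMFLSCFAHDLKWIVLSSQRFADISHSYRFGRTHMMLMNPYQCSFSNAPH
GNNHVYDSADCCQNFYSATGCVWVNWIHIAYRDYCFKYYKWLLHIMISPMWSCKAHTKKQ
IVWSHHRFQKISHCTGFGRYRAGFMWPPQCWFSNAPHQHNHVPDSADGWLISISQSMHGM
>OtherBac_04 synthetic bead-on-a-string protein
AFSGLILEWLNMHIWRNDVCFWYYKWLLHRRTSWMGSCFAHDAKGIVWSSHRFQKISHCM
MFGRYLQAIMWPTQCSGSNAPMQGNHVPDHDDHMYPLAVMATLLQLPMTPLHIYHHIARD
DNCFPYYYWLLHRRTSMFLSCFAHDLKSIVGSSQRFADISHCYCFGRTRMWLMNPYQCSF
SNAPHVNNHVHDSADTTQFDEQHRVHMAGRDGCGKYKKWLLHIRGSPCFSCKAHTKKQIV
WSSTRFQKISHCTGFGKDIAGFMWPPQPSRSNAPHQLNHVGDFADHEVRAVSTYAIWTLL
HAER
>OtherBac_05 synthetic bead-on-a-string protein
SNLTPHVIGSCTNQQEGHIWRNDVNFWYYKWLLHRRTSMEGSCFHHDAKGIVWSSHRFQK
ISHCYMFGRRLQAIWWPTQCSGSNAPHQGNHVPDMDFWGNSMGYNKDHFRTATHHHTYWN
QMHIARRDNCFFYYYWLLHRRTSMFLSCCAHDLKWIVLSSQRFADISHCPCFGRTRMMLM
NPYQCSFSNAPHVGNHVYGSADEHCYWMDTLMDCPEEIQQHIAYRLKKKKYYKWLLHIAI
SPMFSCKAHTKKQIVWSSHRFQKISHCTGFGRYRAGFMWPPQCSFSNAPHQHNHVPDSAD
EHIYVWWFLRVA
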