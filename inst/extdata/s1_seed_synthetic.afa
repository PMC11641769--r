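>SourceBac_01.1
HFTFVDDCVWYQAWELHRRMSPWTSCYAHMQKRIVYSIDVFQAISHNRVFGPDRLIAHQPYQCVFSNAGKLANHVFDGKL
>SourceBac_01.2
HFERRDWCEWYQAWMLHRRMSYWTSCYAHDQKQIVWSIHVFQWISHNRAFGMDSMTIEQPMQCKQSNAPYRLNHVFDGGL
>SourceBac_01.3
HECEREDVEWYQAWFLHRRMSFWTSCEAHDQKQIVYSIWVFQWISHNRKFIMDRMTIEQPYQCVHSNATKPLNHVFDGKL
>SourceBac_02.1
HFTSVFDCFIYQAWELHRRMSPWTSCYAHMQKRIVYSIDVFQAISHNRTFGPSRGIAHQPYQCVFSNAGSRLNHVFDIKL
>SourceBac_02.2
HFERRDVCEWYQAWMLHRRMSYWTSCYWHDQKQIVWSIEVFQWISHNRAFGMESMTIEQPMQCKQSNAPYRLNHVFDGGL
>SourceBac_02.3
HFCEREDVEWYQAWFLHRPMSFWTSCFAHDQKQIVDSIDVFQAISHNRKFGMDQMTIEQPYQCVHSNATKPLNHVFDGKL
>Organelle_01.1
HFCEREDVEWYQAWFLHRRMSFWTSCFAHHQKQIVYSDWVFQSISHNRKFGNDRPTIEQPYQCVHSNATKPLNHVFYGKL
>Organelle_01.2
HFCTREDIELYQAWFLHWRMSFWTSCFAHDQKQIVYSIWVFQAISHNRKFDMDRMTIEQPYQCVHSNATKPLNHVVGGKL
>Organelle_01.3
HTCEREDVEWYQAWFLHRWMSFWTSCFAHDQKYIVYSPWHFQAISHNRKFGMLRMTIEQPVQCVHSNCSKPLNHVFDGKL
>Organelle_02.1
HNCTREDVKWYQAWFLHRLMSFWTSCFAHLQKGIVYSIWVFQNISHNSKFGNDRVTIEQPYQCGHSNATKPLNHVFYGHL
>Organelle_02.2
HNCEREDIEWYQAWFLHRHMSFWTSCFAHDQKQIVYSWWVFQAISHNRKFDMGRMTDEQPYQCHHSNATKPLNHVFGRKL
>Organelle_02.3
HTCEREDTEWYQAWFLHRRMSFWTSCFAHDQKQIVYSIWVFQAISHNRKFGMLRMTIEQPFQCCHSNCDKPENHVFNGKL
>OtherBac_01.1
HIWRNDVCFWYYKWLLHRRTSMMGSCFAHDAKGIVWSSHRFQKISHCEMFGRVLQAIMWPTQMSGSNAPHQGNHVPDPDD
>OtherBac_01.2
HIARRDNNFPYNYWLLHRRTSMFRSCFAHDLKWIVGSSQAFADISHCYCFGRTRMALMNPYQCSFSNAPHVGNHVYDDAD
>OtherBac_01.3
HIKYRDKCFVYYKWLLHIRISPMFVCKAHTKKQIVQSSHRFQKISHCTGFGRYRAGFMWPPQCSFSNLPHQHNHVPDSAD
>OtherBac_02.1
HIRRNKVCFWYYKWLLHRRTSMMTSCFAHDAKGIVWSSHRFQKISHCYMFGRILQAIMWPTQCSGSNAPHQGNHVPDPDD
>OtherBac_02.2
HIARRDLCFPYYYWLLHRPTSMSLSCFAHDVKWIVLSSIRFADISHCYCFGRTRMMLFNPYQSSFSNAPHVGNHVYDSAD
>OtherBac_02.3
HIAYRDKCFKYYKWLLHICPSPMFSCKAHTKKQIVWSSHRFQKISHCTGFGSYRAGFMWPPQCSFSNAPHQHNHVMDSAD
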