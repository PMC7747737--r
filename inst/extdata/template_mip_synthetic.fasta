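>MIPTMPL01 synthetic PIP-like template scaffold (280 aa); annotated positions in template_annotation_synthetic.tsv
MVMMSASVLELCWVDLRVVTAGFTARFLFGIRWLDPWAGFLAKWAFRTADTLKPLVWGLG
RARKLAFTLNYKPQNVEFIFALSLSPQSLSSGEYNASWVNPAGVDAWNLAAVMRISVNNH
GQANTCRDDLQAFFRTAAVSGMIVWPPLYQLWEKILAAGMVSNPGVETSQVNGSLEIFIV
RNEVGAGVPCVLIIHSGENLRGLTFTLVMSALAAISVDNPAAATRFSAHISVYNFLNYVL
RLFYCGGSTFWGLLQSAGFFHLLLTPILMEFMIALFADTA
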