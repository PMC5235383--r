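language,family,source
Afrikaans,Germanic,Leipzig Corpus
Asturian,Romance,UDHR Corpus
Bosnian,Slavic,Leipzig Corpus
Breton,Celtic,UDHR Corpus
Catalan,Romance,Leipzig Corpus
Corsican,Romance,Leipzig Corpus
Czech,Slavic,Leipzig Corpus
Danish,Germanic,Leipzig Corpus
Dutch,Germanic,Leipzig Corpus
English,Germanic,Leipzig Corpus
French,Romance,Leipzig Corpus
Frisian,Germanic,Leipzig Corpus
Friulian,Romance,UDHR Corpus
Galician,Romance,Leipzig Corpus
German,Germanic,Leipzig Corpus
Icelandic,Germanic,Leipzig Corpus
Irish,Celtic,Leipzig Corpus
Italian,Romance,Leipzig Corpus
Latvian,Baltic,Leipzig Corpus
Lithuanian,Baltic,Leipzig Corpus
Luxembourgish,Germanic,Leipzig Corpus
Norwegian,Germanic,Leipzig Corpus
Polish,Slavic,Leipzig Corpus
Portuguese,Romance,Leipzig Corpus
Romanian,Romance,Leipzig Corpus
Scottish,Celtic,Bible Corpus
Serbian,Slavic,HC Corpus
Slovak,Slavic,Leipzig Corpus
Slovenian,Slavic,Leipzig Corpus
Spanish,Romance,Leipzig Corpus
Swedish,Germanic,Leipzig Corpus
Welsh,Celtic,Bible Corpus
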