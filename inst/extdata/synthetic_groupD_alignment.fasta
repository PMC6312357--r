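>AT1G58390 synthetic Group D-like alignment (planted fixture)
YAARDQISYKIPSCFSKKPRCTCGFCNMNGCYGSVAFRMCESIKIAQTYACHRIFEVYWGPVWEEFLANKIWLGLIWHNFRSGNDFWKKPGYLDSNSQHWWMDVQNRLFPLERAKDNVMA
>AT1G58848 synthetic Group D-like alignment (planted fixture)
YTARDQISYKIPSCFSKKPRCTCGFCNMNGCYGSVAFRMCESNKIAQTYACHRIFEVYWGPVWEEFLANEIWLGLIWHNFRSGNAFWKKPGYLDSNWQHMWMDVQNRLFPLERAKDNVMA
>AT1G59218 synthetic Group D-like alignment (planted fixture)
YAARDQMSYKIPSCFSKKPRCTCGFCNMNGCYGSVAFRMCESNKIAQTYACHRIFEVYWGPVWEEFLANECWLGLIWHNFRSGNDFWKKPGYLDSNSQHMWMDVQNRLFPLERAKDAVMA
>AT1G58807 synthetic Group D-like alignment (planted fixture)
YAARDQISYKIPSCFSKKPRCTCGFCNMNGCYGSVAFRMCESNKIAQTYACHRIFEVYWGPVWEEFLANEIWLGLIWHNFRSGNDFWKKPGNLGSNSQHMWMDVQNRLQPLERAKDNVMA
>AT1G59124 synthetic Group D-like alignment (planted fixture)
YAARDQISYKIPLCFSKKPRCTCGFCNMNGCYGSVAFRMCESNKIAQTYACHRPFEVYWGPVWEEFLANEIWLGLIWHNFRSHNDFWKKPGYLDSNSQHMWMDVQNRLFPLERAKDNVMA
>synD_rare_1 synthetic Group D-like alignment (planted fixture)
YAARDQISYKIPSMFSKKPRDFCGFCNMNYCMGAVAFRMCGWNKIAQTYACHRIFEPYWPPVWEEWLANEIWL-LIWHNFRSGNDFWVKPGRLD-NSQAMTMDVQNILFPLERAKDNVMA
>synD_rare_2 synthetic Group D-like alignment (planted fixture)
YAARDQISYKIPSCFSKKPRDTCGFCNM-GCYGRVAFRMCEWNKEATTYACHRIFEPYWGPPWESFL-NRIWLGLIWHNFRSGNDFGKKPMDLDSNSQHMWADVQNILFPLERQKDNVTA
>synD_rare_3 synthetic Group D-like alignment (planted fixture)
IAARDQISYYIPSCFSKKPRDTCGFCNMAGCYGSVAFRGCEWNSIAQTYACHRIFEPTWGPVW-EFLANELWLGDIWHNFRSGNDFWKVHGYLDSNSQHMWMDPQNILFPLVRAKDNV-A
>synD_rare_4 synthetic Group D-like alignment (planted fixture)
MAARDQISYKIPWCFSKKPRDTCGFCNMNGCYGSNAFRMCEWNKRAQDYAC-RIFEPYWGPVWEEFLANEIWLGLLWHNIRSGNDFWVK-GYLLSDSQHCWMDVQNILFILERAKDNVMA
>synD_rare_5 synthetic Group D-like alignment (planted fixture)
YANRDQIEYKIASCFSKKGRDTCGFCNMNGCYGSKAFRMCEWNKIAQVYACHRIFYPYWGPVWEEQFANE-WLGLIIHNFR-GDDFWKDPGYLDSNSQHMWMDVQNILFPLERAKDNVMA
>synD_rare_6 synthetic Group D-like alignment (planted fixture)
YAARDSISYKIPSPFSKKPRDTCGFCNMGGCYGSVAFRMCEWNKIAQTYACHFIFEPY-GPVQEEFLYQEIWLGL-WHNFRSGNDFWKKPCYLDSNSQHMWMDWQNISFPLEKAKDAVMA
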