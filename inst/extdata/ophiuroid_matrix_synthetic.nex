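#NEXUS
[ Synthetic stand-in character matrix: 25 taxa x 68 discrete characters,
  states 0-2 with ? = unknown and - = inapplicable.  Taxon names follow
  the studied ophiuroid lineage; all scores are random placeholders. ]
BEGIN DATA;
  DIMENSIONS NTAX=25 NCHAR=68;
  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS="012";
  MATRIX
    Pradesura_jacobi      010020111112?-?0010?0201-21102??001001000?2201011022?100000000001010
    Ophiopetagno_paicei   21101210??220100??20-1???0010-01000-00110120001000101-00001002120010
    Muldaster_haakei      01?00?1?1?200021111010021110112001101-?0?02000101000220021?0002-0101
    Ophiurina_lymani      00002211000?1?1?1000?1100001110?0000-1111001011021?000??1?11200011??
    Ophiurina_armoricana  20?-21-?010010210001111011010-20??00200?202111011?00?000011110?00020
    Stephanoura_belgica   100021?20010?-0101?002?01?-200-1?00?01?2?101021?000101-0100-1-?10001
    Ophiaulax_decheni     011??0?20-101?20001111-1000122?21011110-1?1011001111?01?1?2002?0120?
    Aganaster_gregarius   01--?21010?10101020-00?2???001?1??000-1010-0010?0000?001201000100010
    Ophiopholis_aculeata  1??1100001?0000-100-12??010111?0011021110?12000210000011001?00011001
    Synthetic_taxon_10    111-00011?10000?0??000110110011?10002010?0101001202--110000010011001
    Synthetic_taxon_11    ?11?11111100111-11001--0100201?2002?00110011?01100200100000010-00000
    Synthetic_taxon_12    011020-011?-1?10201110??11?0001111001-000011?1?011000??001?0-?0?0100
    Synthetic_taxon_13    200101010011110011-2110000?0100001000--0001??0120101101021010?011101
    Synthetic_taxon_14    1120?10?-1?1-1100-1-0001002??012021011100?1120??0-102?0-22101?010011
    Synthetic_taxon_15    0?1201100011-0010220101001?000-0?0110?2210211011??10000?1-111200002?
    Synthetic_taxon_16    2?0?100020000?110110010000102201111-10-010??100000?01001000000?20110
    Synthetic_taxon_17    21100?0?1110100?1101011011110100000200100101101?0?1100?000011102??10
    Synthetic_taxon_18    000?01?100?0110?201100001100001010000110?00-11102?1011110210011?1100
    Synthetic_taxon_19    12?0?11100?0011011?0?1?001-0110111122101-10?-1-00?100110011000-1?11-
    Synthetic_taxon_20    -1121100?1-0??10011?11-02200-0?111?01-10-?2110?2-0010011201-?1?-200?
    Synthetic_taxon_21    0001??100?20000100001110??0?011??10000?1101110-100?10010000???210110
    Synthetic_taxon_22    01?20111?0?110110?1-00202?01110110001?00?011?-0000110-12100?10-?1112
    Synthetic_taxon_23    ?1?000?10000211111110?-0200?0-101101021100?00000111-12100002002??1-?
    Synthetic_taxon_24    0101-10000?0?001?0201-11010?000120010??0111?1??01011?10200201000???1
    Synthetic_taxon_25    110-1111?1001000?100011111000-100102112?0101012110210-11010000?00000
  ;
END;
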