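# Published tetrad region coordinates for 18 representative RefSeq
# chloroplast genomes (deposited coordinates; start > end marks a region
# wrapping the sequence origin). printed_group is the starting-point group
# the table was published under; start_code is the positional code implied
# by the printed coordinates themselves (base 1 at / inside LSC, IRb, SSC,
# IRa -> a/b, c/d, e/f, g/h). The two differ for NC_050170.1, whose printed
# coordinates put base 1 on the first base of the SSC, and for the two
# minimal-gene-content ("i") records, whose positional codes are a and b.
accession	organism	printed_group	start_code	regions
NC_036102.1	Sophora alopecuroides	a	a	LSC:1-84221;IRb:84222-110095;SSC:110096-128234;IRa:128235-154108
NC_056151.1	Sophora moorcroftiana	a	a	LSC:1-83342;IRb:83343-107133;SSC:107134-125139;IRa:125140-148930
NC_062457.1	Zingiber teres	b	b	LSC:163399-88112;IRb:88113-117864;SSC:117865-133646;IRa:133647-163398
NC_062475.1	Solanum velardei	b	b	LSC:155437-86008;IRb:86009-111535;SSC:111536-129909;IRa:129910-155436
NC_038203.1	Machilus pauhoi	c	c	LSC:58951-152621;IRb:1-20074;SSC:20075-38876;IRa:38877-58950
NC_038204.1	Machilus thunbergii	c	c	LSC:58901-152551;IRb:1-20050;SSC:20051-38850;IRa:38851-58900
NC_053720.1	Colobanthus nivicola	d	d	LSC:58978-142328;IRb:142329-16445;SSC:16446-33651;IRa:33652-58977
NC_053721.1	Colobanthus lycopodioides	d	d	LSC:58937-142581;IRb:142582-16439;SSC:16440-33616;IRa:33617-58936
NC_057956.1	Camellia achrysantha	e	e	LSC:44327-130575;IRb:130576-156658;SSC:1-18243;IRa:18244-44326
NC_057957.1	Camellia chrysanthoides	e	e	LSC:44332-130895;IRb:130896-156959;SSC:1-18267;IRa:18268-44331
NC_048463.1	Wolffia globosa	f	f	LSC:45381-137551;IRb:137552-169361;SSC:169362-13570;IRa:13571-45380
NC_050170.1	Cyperus rotundus	f	e	LSC:47738-148698;IRb:148699-186119;SSC:1-10315;IRa:10316-47737
NC_050999.1	Heterotis rotundifolia	g	g	LSC:26740-112476;IRb:112477-139215;SSC:139216-156336;IRa:1-26739
NC_056142.1	Verbena officinalis	g	g	LSC:25809-110326;IRb:110327-136134;SSC:136135-153491;IRa:1-25808
NC_062509.1	Solanum caripense	h	h	LSC:2-85726;IRb:85727-109824;SSC:109825-130908;IRa:130909-1
NC_060516.1	Cymbidium cyperifolium	h	h	LSC:688-85961;IRb:85962-111550;SSC:111551-127763;IRa:127764-687
NC_053746.1	Rhododendron platypodum	i	a	LSC:1-109134;IRb:109135-153784;SSC:153785-156397;IRa:156398-201047
NC_061648.1	Larix kongboensis	i	b	LSC:91317-34931;IRb:34932-35367;SSC:35368-90880;IRa:90881-91316
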