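"country_code","p_tilde","omega","T_mid","r_tilde","rho","t_r","alpha"
"C01",0.0372787391477047,0.0942006628094561,2015.74873401136,0.909070253177589,0.0986994709580713,1990.85647152821,-3.80274165155443
"C02",0.436049641711976,0.0823632789406278,2009.60336633497,0.936826089179185,0.0893501925102908,2000.71971769644,-0.222903081723335
"C03",0.243241287900571,0.0953909527030333,2007.09147283861,0.927427988455452,0.0893781993568177,2002.81663834288,0.702039767260455
"C04",0.385149231573433,0.11605724402764,2008.69625113507,0.860282391549321,0.0758622557071838,1992.8024958915,0.0336961096858595
"C05",0.436188469403411,0.106550896320987,1996.09207362231,0.833700833443026,0.113832600994033,1978.84742666734,0.552332144554714
"C06",0.0810545959274282,0.129946855676855,2007.21956226375,0.925711253273047,0.101634827025419,1990.46553374882,-4.0750067541343
"C07",0.06216741432577,0.130317944816461,1996.47099579681,0.913348427144173,0.0937067100813803,1984.76402680005,-3.6959016817276
"C08",0.481868492065379,0.11502219931631,2005.28184549337,0.824881154992965,0.074740616361482,1995.9922905541,-0.243134278979995
"C09",0.587974806901503,0.116439483890542,2002.37478845001,0.853368371322492,0.0575200442961725,1992.31192949711,-0.387484639072131
"C10",0.544098760756402,0.11218175761684,1993.51647922638,0.909919221068931,0.079966147222198,1989.62771332666,-0.465722419247663
"C11",0.0260784452996291,0.117804569775473,1986.8119891937,0.862764387405507,0.0941032294252038,1997.98221104123,-4.65974563707465
"C12",0.557293151950801,0.130965074979769,1981.59846639656,0.896010155303079,0.0823771125189856,1989.57862751602,-0.270848030065364
"C13",0.0279108330465518,0.105797089042532,2002.82558005545,0.87220700136859,0.121268280585226,1994.80834933379,-3.96801785360669
"C14",0.709080016597551,0.100827626185686,1979.90335088506,0.838506655845309,0.115086226488095,2004.38879492127,-0.642570232534148
"C15",0.0181181730756376,0.0929481825996903,2004.58315904566,0.880162987730986,0.120403977555077,2001.57829965387,-3.47339884837903
"C16",0.623778858721339,0.112845220307085,1997.18515353494,0.811970047530641,0.124326625214719,2007.75723311972,-0.438913680196251
"C17",0.563960144430627,0.130647244107228,2000.8051350885,0.848370872106713,0.113334380029407,2003.08705421146,0.130793637819574
"C18",0.46370743225171,0.105915038520199,2002.28930774667,0.898404718726643,0.109444939502582,2005.51215811799,0.000445866848740512
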