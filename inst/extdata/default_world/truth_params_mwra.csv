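"country_code","p_tilde","omega","T_mid","r_tilde","rho","t_r","alpha"
"C01",0.631885278259087,0.102731864780634,1992.42393169724,0.629410598233004,0.102676940457221,1998.75371154063,-0.0339177328162952
"C02",0.740842140301776,0.121386017465437,2003.71839878456,0.81880647363806,0.0874620014899264,1998.39687115863,-0.0503155027667784
"C03",0.773497426773587,0.122143289329741,1988.01084762278,0.723956444238879,0.0956362348222609,1987.05566785846,-0.0100464956220211
"C04",0.788698741490108,0.114668136058609,2003.69290912951,0.835959728190556,0.0951059475957465,1985.26418497144,-0.0901875849101764
"C05",0.697463301009706,0.133021855590852,1993.47154795256,0.611101759730313,0.0834337004749196,1998.10785825632,0.61130770639102
"C06",0.641597028259298,0.136182216626949,2004.39711581546,0.759305750072476,0.108689467670114,1992.27719053234,0.04022436049348
"C07",0.643359527189024,0.132578996014414,1990.65176059057,0.630247422641662,0.148772479092841,1995.31017329651,-0.000790549414230392
"C08",0.753124692913235,0.153598324510946,1992.35422992242,0.83872176567746,0.136024056479369,1993.18656304506,0.287596849774616
"C09",0.670924277500869,0.121618029182876,1982.6322631735,0.75003749585278,0.145392391409459,1985.18202599866,0.365150442108921
"C10",0.835959632963963,0.119933077483451,1973.47905787872,0.719201909430252,0.102500740699562,1981.58344744292,0.358470053928192
"C11",0.668493015601734,0.131722361344357,1990.05576381845,0.841696233842715,0.106889516118997,1991.70532388468,0.162917383483893
"C12",0.69911861283138,0.167666044794909,1986.15271733416,0.810268070146028,0.0852760520389154,1989.79995319267,0.547157257422565
"C13",0.699342799880595,0.170750631060047,2000.35202648156,0.793970739683858,0.139409145169949,1995.52896014074,-0.466257629096587
"C14",0.826586505045069,0.144997985480851,2003.94680578344,0.723617409370533,0.114150950666477,1992.03598795718,-0.697337610819768
"C15",0.84360728070396,0.130610719811737,2008.4376519995,0.601339784851377,0.105390095873058,1999.16765269888,-0.233185691876668
"C16",0.873799262344141,0.155831918321795,2007.55772978487,0.654468327597213,0.131988701246825,2001.0528270672,0.285628317665878
"C17",0.70086039477629,0.102810932697837,2006.62612212105,0.64831688254377,0.110819438289467,1993.85495015759,0.139575846722926
"C18",0.809049734781365,0.108968526897375,2007.09180992076,0.755830480003964,0.10884625624491,1989.68529074896,0.15668932709495
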