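mesocosm_id,taxon_id,count,lengths,widths
M001,bact_nematode_1,20,,
M001,bact_nematode_2,27,,
M001,bact_nematode_3,16,,
M001,bact_nematode_4,9,,
M001,chilopod_1,5,4.8860562;4.5477033;4.2569688;4.2363037;3.8634317,0.97721124;0.90954066;0.85139375;0.84726074;0.77268635
M001,chilopod_2,2,5.6454554;5.1567724,1.1290911;1.0313545
M001,collembola_1,16,0.3131611;0.3063917;0.31313498;0.31530324;0.31428338;0.3582238;0.33963232;0.32924094;0.30993635;0.31167395,
M001,collembola_2,3,0.50685814;0.4929227;0.51985511,
M001,collembola_3,3,0.77904739;0.68347331;0.84317251,
M001,diplopod_1,3,8.0709063;7.876666;8.8225059,1.6141813;1.5753332;1.7645012
M001,earthworm_1,1,9.6222855,1.9244571
M001,earthworm_2,3,11.284346;11.872541;11.190422,2.2568692;2.3745082;2.2380845
M001,enchytraeid_1,2,0.82122479;0.92106501,
M001,enchytraeid_2,0,,
M001,fung_nematode_1,7,,
M001,fung_nematode_2,2,,
M001,herb_larva_1,5,4.8491727;4.7199957;4.4458214;4.8977055;4.7699094,0.96983455;0.94399915;0.88916427;0.9795411;0.95398187
M001,herb_nematode_1,6,,
M001,herb_nematode_2,6,,
M001,isopod_1,1,6.3777942,1.2755588
M001,omni_nematode_1,1,,
M001,omni_nematode_2,0,,
M001,oribatid_1,30,0.40368;0.47973582;0.40650961;0.38887757;0.42085858;0.42092834;0.36767054;0.45657864;0.3843659;0.43132965,
M001,oribatid_2,17,0.44070011;0.42842023;0.41979148;0.4304488;0.38936217;0.39763735;0.38797444;0.48026517;0.47714526;0.43266961,
M001,oribatid_3,7,0.59978739;0.6611276;0.74545278;0.63686551;0.7044732;0.61221553;0.69844175,
M001,pred_mite_1,3,0.50652608;0.55769714;0.67802508,
M001,pred_mite_2,2,0.89479702;0.81734975,
M001,pred_nematode_1,4,,
M001,pred_nematode_2,2,,
M001,spider_1,4,3.6382201;4.4976895;3.6593856;3.8337956,0.72764403;0.89953791;0.73187713;0.76675913
M002,bact_nematode_1,35,,
M002,bact_nematode_2,26,,
M002,bact_nematode_3,12,,
M002,bact_nematode_4,1,,
M002,chilopod_1,4,3.7973335;3.6753366;3.8251649;4.0156342,0.7594667;0.73506732;0.76503298;0.80312684
M002,chilopod_2,1,4.9904322,0.99808644
M002,collembola_1,16,0.3248007;0.34555038;0.29672994;0.32585532;0.30398098;0.29355083;0.32869433;0.30633967;0.28070587;0.29972898,
M002,collembola_2,17,0.53080976;0.51739753;0.42009536;0.47508171;0.50426712;0.41458568;0.52717826;0.45170991;0.48204222;0.46432783,
M002,collembola_3,3,0.88016956;0.69115766;0.76800852,
M002,diplopod_1,2,7.0077907;8.5142762,1.4015581;1.7028552
M002,earthworm_1,2,10.316531;11.266047,2.0633063;2.2532093
M002,earthworm_2,0,,
M002,enchytraeid_1,2,0.77534125;0.88633039,
M002,enchytraeid_2,1,1.0335668,
M002,fung_nematode_1,15,,
M002,fung_nematode_2,0,,
M002,herb_larva_1,5,4.5978924;4.6467663;4.1202984;4.8021088;4.7777388,0.91957848;0.92935325;0.82405968;0.96042175;0.95554775
M002,herb_nematode_1,1,,
M002,herb_nematode_2,3,,
M002,isopod_1,1,6.6246917,1.3249383
M002,omni_nematode_1,3,,
M002,omni_nematode_2,0,,
M002,oribatid_1,15,0.35141772;0.39806321;0.38416251;0.36566741;0.37289115;0.3474019;0.36246946;0.40189901;0.36780875;0.37304768,
M002,oribatid_2,17,0.50644738;0.40800551;0.46551118;0.49713508;0.39651953;0.43199856;0.41827445;0.41494372;0.39709941;0.40183039,
M002,oribatid_3,2,0.73920072;0.70068248,
M002,pred_mite_1,3,0.52610731;0.58594154;0.67695864,
M002,pred_mite_2,2,0.70539076;0.79142679,
M002,pred_nematode_1,3,,
M002,pred_nematode_2,1,,
M002,spider_1,3,4.1101899;3.6526125;2.9504494,0.82203799;0.73052251;0.59008989
M003,bact_nematode_1,42,,
M003,bact_nematode_2,30,,
M003,bact_nematode_3,5,,
M003,bact_nematode_4,1,,
M003,chilopod_1,1,3.6081984,0.72163968
M003,chilopod_2,0,,
M003,collembola_1,112,0.35819559;0.35413182;0.39424137;0.3383469;0.30991417;0.34565115;0.33765521;0.36166173;0.39146388;0.29801736,
M003,collembola_2,35,0.47298023;0.48375141;0.5024736;0.45522727;0.49617882;0.49581912;0.48059112;0.47634368;0.54033424;0.50744255,
M003,collembola_3,9,0.84775408;0.71073248;0.6578778;0.70363682;0.73166602;0.71246046;0.70273859;0.64076732;0.68160545,
M003,diplopod_1,0,,
M003,earthworm_1,0,,
M003,earthworm_2,0,,
M003,enchytraeid_1,4,0.68315574;0.629303;0.71051722;0.76247086,
M003,enchytraeid_2,1,1.1549215,
M003,fung_nematode_1,14,,
M003,fung_nematode_2,3,,
M003,herb_larva_1,0,,
M003,herb_nematode_1,2,,
M003,herb_nematode_2,1,,
M003,isopod_1,0,,
M003,omni_nematode_1,0,,
M003,omni_nematode_2,0,,
M003,oribatid_1,159,0.43628223;0.40821563;0.37854134;0.37364541;0.39459337;0.35056491;0.37925003;0.3867576;0.39285673;0.34377466,
M003,oribatid_2,44,0.50873935;0.47900564;0.55263536;0.3900874;0.43240807;0.39554927;0.43822949;0.46436055;0.51851305;0.43745302,
M003,oribatid_3,20,0.52559078;0.56403837;0.60708573;0.58632941;0.64156574;0.56441702;0.50719983;0.6231871;0.52916163;0.60688918,
M003,pred_mite_1,10,0.60346802;0.67448994;0.67644226;0.7435973;0.64125707;0.70957198;0.63369538;0.58378274;0.68126825;0.63167652,
M003,pred_mite_2,5,0.7803789;0.78521022;0.90886613;0.9443095;0.90297151,
M003,pred_nematode_1,0,,
M003,pred_nematode_2,2,,
M003,spider_1,0,,
M004,bact_nematode_1,47,,
M004,bact_nematode_2,23,,
M004,bact_nematode_3,2,,
M004,bact_nematode_4,4,,
M004,chilopod_1,0,,
M004,chilopod_2,1,5.2812891,1.0562578
M004,collembola_1,145,0.35863724;0.33545495;0.29025265;0.33342911;0.29007235;0.31664278;0.35616332;0.28816616;0.33304054;0.31470164,
M004,collembola_2,74,0.45602543;0.50458695;0.48421646;0.51746787;0.42693839;0.43595217;0.43992404;0.46226539;0.43140567;0.43766819,
M004,collembola_3,3,0.73775669;0.83604847;0.83237938,
M004,diplopod_1,0,,
M004,earthworm_1,0,,
M004,earthworm_2,0,,
M004,enchytraeid_1,5,0.95244603;0.93163688;0.90040551;0.80402266;0.97843935,
M004,enchytraeid_2,2,1.1564354;1.2674369,
M004,fung_nematode_1,15,,
M004,fung_nematode_2,3,,
M004,herb_larva_1,0,,
M004,herb_nematode_1,1,,
M004,herb_nematode_2,2,,
M004,isopod_1,0,,
M004,omni_nematode_1,3,,
M004,omni_nematode_2,0,,
M004,oribatid_1,99,0.37076816;0.3407486;0.37733388;0.36591227;0.36626536;0.35851653;0.3323668;0.34758814;0.38709063;0.36542363,
M004,oribatid_2,37,0.48984064;0.48210426;0.54668364;0.48998962;0.49902709;0.49509053;0.45332781;0.48670323;0.54178313;0.50735507,
M004,oribatid_3,11,0.58793793;0.66366224;0.68952274;0.65570402;0.70180065;0.65064766;0.60690138;0.69884668;0.67347714;0.6886364,
M004,pred_mite_1,10,0.61126429;0.70188773;0.56040127;0.60016055;0.73633682;0.5942746;0.56536138;0.52631431;0.54437241;0.49728313,
M004,pred_mite_2,2,0.79446897;0.8714431,
M004,pred_nematode_1,0,,
M004,pred_nematode_2,0,,
M004,spider_1,0,,
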