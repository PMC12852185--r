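row,colony_id,name,coords,region,r,lambda,ci_low,ci_high,significant
1,BSA,Bahía San Antonio,40°47'S 64°47'W,Río Negro,-0.0101,0.99,0.74,1.35,FALSE
2,ILP,Islote La Pastosa,41°25'S 65°02'W,Río Negro,0.0159,1.02,0.96,1.08,FALSE
3,IR,Islote Redondo,41°26'S 65°01'W,Río Negro,0.1970,1.22,1.13,1.31,TRUE
4,IP,Isla de los Pájaros,41°27'S 65°02'W,Río Negro,-0.0896,0.91,0.79,1.06,FALSE
5,PP,Punta Pozos,41°34'S 65°01'W,Río Negro,-0.3164,0.73,NA,NA,FALSE
6,IN,Islote Notable,42°25'S 64°31'W,Chubut,0.1768,1.19,1.10,1.29,TRUE
7,ESL,Estancia San Lorenzo,42°05'S 63°51'W,Chubut,0.1989,1.22,1.16,1.28,TRUE
8,AO,Asentamiento Oeste,42°06'S 63°56'W,Chubut,0.0441,1.05,1.01,1.09,TRUE
9,CE,Caleta Externa,42°16'S 63°38'W,Chubut,0.0916,1.10,1.07,1.13,TRUE
10,I1°,Isla Primera,42°21'S 63°37'W,Chubut,0.0451,1.05,1.02,1.07,TRUE
11,I2°,Isla Segunda,42°20'S 63°39'W,Chubut,0.1474,1.16,1.16,1.20,TRUE
12,CI,Caleta Interna,42°27'S 63°36'W,Chubut,-0.0179,0.98,0.96,1.01,FALSE
13,EP,El Pedral,42°57'S 64°23'W,Chubut,0.5622,1.76,1.42,2.11,TRUE
14,PC,Punta Clara,43°58'S 65°15'W,Chubut,-0.0188,0.98,NA,NA,FALSE
15,PT,Punta Tombo,44°02'S 65°11'W,Chubut,-0.0167,0.98,0.98,0.99,TRUE
16,PL,Punta Lobería,44°35'S 65°22'W,Chubut,0.0445,1.05,NA,NA,FALSE
17,IBM,Isla Blanca Mayor,44°46'S 65°38'W,Chubut,-0.0403,0.96,NA,NA,FALSE
18,CDB,Cabo Dos Bahías,44°54'S 65°32'W,Chubut,-0.0030,1.00,0.99,1.01,FALSE
19,IA,Isla Arce,45°00'S 65°29'W,Chubut,-0.0820,0.92,NA,NA,FALSE
20,IL,Isla Leones,45°03'S 65°36'W,Chubut,-0.0675,0.94,0.92,0.95,TRUE
21,Pla,Península Lanaud,45°03'S 65°35'W,Chubut,-0.0044,1.00,NA,NA,FALSE
22,IB,Isla Buque,45°03'S 65°37'W,Chubut,-0.0236,0.98,NA,NA,FALSE
23,ISO,Isla Sudoeste,45°03'S 65°36'W,Chubut,-0.0778,0.93,NA,NA,FALSE
24,IT,Isla Tova,45°06'S 66°00'W,Chubut,-0.0231,0.98,NA,NA,FALSE
25,ITa,Isla Tovita,45°07'S 65°57'W,Chubut,-0.0631,0.94,0.92,0.96,TRUE
26,IE,Isla Este,45°07'S 65°56'W,Chubut,0.1279,1.14,NA,NA,FALSE
27,IG,Isla Gaviota,45°06'S 65°58'W,Chubut,-0.0498,0.95,0.951,0.952,TRUE
28,IVN1,Isla Vernaci Norte,45°11'S 66°30'W,Chubut,0.0058,1.01,0.99,1.03,FALSE
29,IVN2,Isla Vernaci Norte2,45°11'S 66°30'W,Chubut,0.0112,1.01,1.00,1.02,FALSE
30,IVE,Isla Vernaci Este,45°11'S 66°29'W,Chubut,-0.0216,0.98,0.96,1.00,FALSE
31,IVNO,Isla Vernaci Noroeste,45°10'S 66°31'W,Chubut,0.1136,1.12,1.03,1.21,TRUE
32,IVSO,Isla Vernaci Sudoeste,45°11'S 66°31'W,Chubut,-0.0195,0.98,0.96,1.00,FALSE
33,IVF1,Isla Vernaci Fondo1,45°11'S 66°30'W,Chubut,-0.0022,1.00,NA,NA,FALSE
34,PPaj,Punta Pájaros,46°57'S 66°51'W,Santa Cruz,0.0394,1.04,NA,NA,FALSE
35,ICh,Isla Chaffers,47°46'S 65°52'W,Santa Cruz,0.0009,1.00,0.99,1.01,FALSE
36,IPa,Isla Pájaros,47°45'S 65°58'W,Santa Cruz,0.0197,1.02,1.01,1.03,TRUE
37,IQ,Isla Quiroga,47°45'S 65°56'W,Santa Cruz,0.0334,1.03,1.03,1.04,TRUE
38,ILg,Isla Larga,47°45'S 65°56'W,Santa Cruz,0.0896,1.09,NA,NA,FALSE
39,ICP,Islote Cañadon del Puerto,47°45'S 66°00'W,Santa Cruz,-0.0109,0.99,NA,NA,FALSE
40,IdR,Isla del Rey,47°46'S 66°03'W,Santa Cruz,-0.0138,0.99,NA,NA,FALSE
41,IBti,Islote Burlotti,47°46'S 65°57'W,Santa Cruz,0.0098,1.01,NA,NA,FALSE
42,IPno,Isla Pingüino,47°54'S 65°43'W,Santa Cruz,-0.0177,0.98,NA,NA,FALSE
43,ICta,Isla Chata,47°56'S 65°44'W,Santa Cruz,0.0312,1.03,NA,NA,FALSE
44,ISch,Isla Schwarz,48°04'S 65°54'W,Santa Cruz,-0.0053,0.99,NA,NA,FALSE
45,IteB,Islote Burgos,48°05'S 65°54'W,Santa Cruz,-0.0235,0.98,NA,NA,FALSE
46,ILi,Isla Liebres,48°06'S 65°54'W,Santa Cruz,-0.0277,0.97,NA,NA,FALSE
47,PM,Punta Medanosa,48°06'S 65°55'W,Santa Cruz,-0.0519,0.95,NA,NA,FALSE
48,PS,Punta Sur,48°07'S 65°56'W,Santa Cruz,0.0253,1.03,NA,NA,FALSE
49,E8J,Estancia 8 de Julio,48°07'S 66°08'W,Santa Cruz,0.0490,1.05,1.04,1.06,TRUE
50,IRC,Isla Rasa Chica,48°22'S 66°20'W,Santa Cruz,-0.0466,0.95,NA,NA,FALSE
51,Iba,Islote del Bajío,48°21'S 66°21'W,Santa Cruz,0.1149,1.12,NA,NA,FALSE
52,IsN,Islote sin Nombre,48°22'S 66°21'W,Santa Cruz,-0.0224,0.98,NA,NA,FALSE
53,CG,Cabo Guardián,48°21'S 66°21'W,Santa Cruz,0.0142,1.01,1.01,1.02,TRUE
54,BC,Banco Cormorán,49°16'S 67°40'W,Santa Cruz,0.0081,1.01,0.99,1.02,FALSE
55,BJ,Banco Justicia,49°17'S 67°41'W,Santa Cruz,-0.0433,0.96,NA,NA,FALSE
56,IL(SC),Isla Leones (Sta Cruz),50°04'S 68°26'W,Santa Cruz,0.0053,1.01,NA,NA,FALSE
57,PE,Punta Entrada,50°08'S 68°22'W,Santa Cruz,-0.0128,0.99,NA,NA,FALSE
58,ML,Monte León,50°22'S 68°53'W,Santa Cruz,0.0137,1.01,1.01,1.02,TRUE
59,ID,Isla Deseada,51°34'S 69°02'W,Santa Cruz,0.0036,1.00,0.97,1.03,FALSE
60,CV,Cabo Vírgenes,52°22'S 68°24'W,Santa Cruz,0.0132,1.01,1.01,1.02,TRUE
61,IMar,Isla Martillo,54°54'S 67°22'W,Tierra del Fuego,0.0624,1.06,1.04,1.09,TRUE
62,BF,Bahía Franklin,54°52'S 64°42'W,Tierra del Fuego,0.1076,1.11,NA,NA,FALSE
63,IGo,Isla Gofré,54°42'S 64°14'W,Tierra del Fuego,-0.0634,0.94,NA,NA,FALSE
64,SJS,San Juan de Salvamento,54°43'S 63°48'W,Tierra del Fuego,0.0733,1.08,NA,NA,FALSE
65,IM,Islas Malvinas,51°47'S 59°31'W,Malvinas,-0.0855,0.92,NA,NA,FALSE
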