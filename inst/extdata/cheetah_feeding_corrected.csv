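date,individual_id,species,common_name,proportion
03.11.2017,Jura,Cervus spp,Deer,0.47
03.11.2017,Jura,Gallus gallus,Chicken,0.18
03.11.2017,Jura,Oryctolagus cuniculus,Rabbit,0.35
04.11.2017,Jura,Cervus spp,Deer,0.47
04.11.2017,Jura,Gallus gallus,Chicken,0.29
04.11.2017,Jura,Oryctolagus cuniculus,Rabbit,0.24
05.11.2017,Jura,Cervus spp,Deer,0.82
05.11.2017,Jura,Gallus gallus,Chicken,0.18
06.11.2017,Innis,Cervus spp,Deer,0.56
06.11.2017,Innis,Equus caballus,Horse,0.27
06.11.2017,Innis,Gallus gallus,Chicken,0.17
06.11.2017,Jura,Cervus spp,Deer,0.82
06.11.2017,Jura,Gallus gallus,Chicken,0.18
07.11.2017,Innis,Equus caballus,Horse,0.61
07.11.2017,Innis,Meleagris gallopavo,Turkey,0.06
07.11.2017,Innis,Gallus gallus,Chicken,0.33
07.11.2017,Jura,Cervus spp,Deer,0.82
07.11.2017,Jura,Gallus gallus,Chicken,0.18
08.11.2017,Innis,Cervus spp,Deer,0.56
08.11.2017,Innis,Oryctolagus cuniculus,Rabbit,0.06
08.11.2017,Innis,Coturnix coturnix,Quail,0.38
08.11.2017,Jura,Cervus spp,Deer,0.88
08.11.2017,Jura,Gallus gallus,Chicken,0.06
08.11.2017,Jura,Oryctolagus cuniculus,Rabbit,0.06
09.11.2017,Innis,Equus caballus,Horse,0.11
09.11.2017,Innis,Oryctolagus cuniculus,Rabbit,0.06
09.11.2017,Innis,Gallus gallus,Chicken,0.83
09.11.2017,Jura,Cervus spp,Deer,0.88
09.11.2017,Jura,Equus caballus,Horse,0.12
10.11.2017,Innis,Oryctolagus cuniculus,Rabbit,0.17
10.11.2017,Innis,Gallus gallus,Chicken,0.83
10.11.2017,Jura,Cervus spp,Deer,0.88
10.11.2017,Jura,Gallus gallus,Chicken,0.12
11.11.2017,Innis,Equus caballus,Horse,0.33
11.11.2017,Innis,Gallus gallus,Chicken,0.67
11.11.2017,Jura,Cervus spp,Deer,0.88
11.11.2017,Jura,Gallus gallus,Chicken,0.12
12.11.2017,Innis,Cervus spp,Deer,0.89
12.11.2017,Innis,Gallus gallus,Chicken,0.11
12.11.2017,Jura,Cervus spp,Deer,0.88
12.11.2017,Jura,Gallus gallus,Chicken,0.12
13.11.2017,Innis,Cervus spp,Deer,1.0
13.11.2017,Jura,Cervus spp,Deer,0.88
13.11.2017,Jura,Gallus gallus,Chicken,0.12
14.11.2017,Innis,Oryctolagus cuniculus,Rabbit,0.22
14.11.2017,Innis,Gallus gallus,Chicken,0.78
14.11.2017,Jura,Cervus spp,Deer,0.88
14.11.2017,Jura,Gallus gallus,Chicken,0.12
15.11.2017,Innis,Oryctolagus cuniculus,Rabbit,0.22
15.11.2017,Innis,Gallus gallus,Chicken,0.78
15.11.2017,Jura,Cervus spp,Deer,0.88
15.11.2017,Jura,Gallus gallus,Chicken,0.12
16.11.2017,Jura,Cervus spp,Deer,0.88
16.11.2017,Jura,Gallus gallus,Chicken,0.12
17.11.2017,Jura,Cervus spp,Deer,0.88
17.11.2017,Jura,Gallus gallus,Chicken,0.12
18.11.2017,Jura,Cervus spp,Deer,0.88
18.11.2017,Jura,Gallus gallus,Chicken,0.12
19.11.2017,Jura,Cervus spp,Deer,0.88
19.11.2017,Jura,Gallus gallus,Chicken,0.12
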