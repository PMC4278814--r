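site,latitude,longitude,elevation_m,n,na,ar,he,fis
Ardene,43.89,5.73,495,30,3.3,2.738,0.442,-0.012
Castellane,43.86,6.52,1005,32,3.5,3.076,0.552,0.061
F.D. Lure,44.07,5.79,960,30,3.1,2.739,0.497,0.008
F.D. Venasque,43.98,5.21,320,30,3.3,2.940,0.531,-0.024
Foret de Barres,44.66,4.73,470,9,2.3,2.500,0.417,-0.173
Gap,44.55,6.00,990,30,3.0,2.759,0.456,0.020
Grand Luberon,43.81,5.47,1100,30,2.9,2.813,0.513,-0.031
Luberon crete,43.80,5.24,670,278,5.6,3.097,0.491,0.083
Mirabel,44.61,4.51,590,46,2.7,2.159,0.324,0.413
Mont Ventoux,44.14,5.39,1085,30,3.6,3.238,0.558,0.072
Saou,44.65,5.13,475,30,3.0,3.159,0.539,0.184
Saumon,44.10,6.17,600,27,2.5,2.694,0.482,0.060
Sisteron,44.24,5.92,500,29,3.1,3.116,0.522,0.246
Vesc,44.53,5.11,655,30,3.1,2.846,0.482,-0.099
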