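species,n_samples,concentration_pct,sucrose_pct,sucrose_sd,glucose_pct,glucose_sd,fructose_pct,fructose_sd,amount_ug,amount_sd
Acanthonema strigosum,5,8.97,93.0,5.7,3.7,2.6,3.3,3.2,150.5,76.5
Acanthopale decempedalis,15,6.93,73.1,9.6,9.7,4,17.2,5.7,386.1,220.6
Aframomum sp. purple,38,17.71,34.0,25.3,35.0,11.6,31.1,15.6,763,863
Argocoffeopsis afzelii,4,,35.5,8.9,35.1,1.1,29.4,9.7,120.8,90.7
Baccharoides calvoana,14,44.44,39.9,6.4,27.9,3.7,32.2,3.7,189.9,110.6
Bertiera racemosa,3,18.43,24.1,4.7,45.1,4.7,30.7,7.8,628.3,476.5
Brillantaisia owariensis,24,30.2,56.9,10.3,19.7,8,23.4,5.7,1295.3,1024.4
Calochone acuminata,4,20.75,21,6.8,13.2,0.2,65.7,6.9,8742.7,3191.5
Chlorophytum comosum,6,,0.2,0.2,49.5,7.2,50.3,7.2,27.2,19.7
Clematis simensis,3,,78.1,14.8,14.5,10.6,7.3,4.2,9.4,1.6
Clerodendrum silvanum,17,11.69,65.3,15.5,20.4,8.3,14.2,8.2,279.2,210.2
Costus dubius,7,18.6,77.2,20,7.6,9.2,15.3,13.7,2755.6,3435
Crassocephalum montuosum,6,,36.5,26.6,27.5,16.7,36,15.1,13.5,7.4
Cuviera longiflora,3,,51,14.3,19.5,5.7,29.4,8.6,1627.3,616.9
Deinbollia sp. 1,15,,66.1,21.7,16.4,12.1,17.5,10.3,164.5,119.1
Dicranolepis vestita,6,20.25,94.3,2.9,2.8,1.5,2.9,1.5,422.2,283.8
Dioscoreophyllum cumminsii,4,,1.7,3.3,33.3,17.7,65,14.7,4.3,2.4
Dischistocalyx strobilinus,31,17.03,50.1,19.7,30,10.5,19.9,13,617.4,595.6
Discoclaoxylon hexandrum,8,,88.2,8,6.5,4.8,5.4,3.4,7.4,5.3
Discopodium penninervium,5,,23.5,8.9,37.3,4.2,39.3,5.1,238.7,162.2
Distephanus biafrae,5,,20.7,12.3,42.7,7.3,36.6,6.7,154.7,94.2
Gomphia flava,5,,2.6,2.1,54.4,2.6,43,3.3,7.7,4.9
Heckeldora staudtii,5,,67.1,11.8,11.9,3.1,21,8.9,74.7,19.2
Heinsia crinita,3,23.5,46.8,28.6,17.3,14.8,35.9,28.9,352.7,143.3
Hypoestes triflora,20,17.88,32.6,11.5,41.4,9.1,26,5.8,229.6,164
Ilex mitis,7,37.9,48.8,10.7,22.6,5,28.6,6.3,78.2,92.9
Impatiens burtonii,18,30.82,78.3,19.4,14.1,12.7,7.6,7.2,423.3,358.1
Impatiens frithii,11,16.12,85,10.4,7.2,5,7.8,5.6,957.3,645
Impatiens hians,20,19.75,95.3,5.6,1.7,1.9,2.9,4.1,2107.7,1758.9
Impatiens macroptera,25,26.01,88.2,21,6.9,13,4.9,8.2,786.5,691.9
Impatiens mannii,13,,64,35.5,21,20.4,15.1,15.1,59.1,66.3
Impatiens niamniamensis,46,15.95,82,16.8,8.8,8.5,9.2,8.9,1819.7,1530.4
Impatiens sakeriana,7,19.7,81.4,14.9,9,7.3,9.6,7.8,2345.4,1583.2
Isodon ramosissimus,14,15.62,56.8,10.6,26.3,6.9,16.9,4,100.5,30.6
Isoglossa glandulifera,10,6.5,77.1,9.1,9.2,5,13.7,6.3,43.4,25.3
Ixora foliosa,9,13.88,94.6,1.9,2.4,1,3,1.1,98,34.2
Ixora guineensis,18,12.09,76.8,17.7,9.7,8.4,13.5,11.1,59,58.2
Laccodiscus ferrugineus,17,,46.8,36.4,23.5,18.9,29.7,21.3,137,123.2
Melanthera scandens,13,,44,23.2,30.8,16.9,25.2,11,13.1,14.1
Mikania cordata,15,,41.8,20.2,15.9,8.2,42.4,14,5.6,4.1
Nuxia congesta,5,23.06,50.4,4.5,24.4,3,25.2,1.9,386.3,117.7
Oncoba dentata,3,,2.4,2.1,44.5,8.9,53,9.1,7.6,3.4
Pavetta hookeriana,9,31.58,33.9,13,31,6.3,35.1,7.3,244.4,218.1
Pavetta neurocarpa,15,23.68,58,12.4,23.5,7.5,18.4,5.9,185.1,103.9
Pavetta rigida,19,12.36,45.2,11.3,26.8,5.6,28,10,562.8,549.5
Plectranthus decurrens,20,19.21,74.6,8.7,20.8,6,4.7,3.4,121,71.3
Plectranthus glandulosus,15,36.05,67.4,12.3,18.2,5.3,14.4,7.3,320.9,160.7
Plectranthus kamerunensis,18,29.24,72.3,8.8,23.3,7.2,4.4,2.4,478.5,353.3
Psychotria bifaria,10,,21.9,32.2,38.8,15.2,39.3,17.6,58.3,57.5
Psychotria leptophylla,11,,31.6,35.3,34.6,17.7,33.8,17.7,101.6,40.5
Psychotria peduncularis,16,14.13,66.7,17,16,6.8,17.3,10.7,332,324.5
Psychotria thonneri,7,9.9,80.8,16.8,11.4,11.4,7.8,5.7,182.4,129.7
Psydrax dunlapii,3,11.5,68.4,2.9,14.5,2,17.2,1,102.1,32.6
Sabicea calycina,15,24.35,77.2,22.8,13,8.7,9.9,17.1,346.8,234.7
Sabicea pilosa,16,18.34,68,17.8,17.1,9.3,14.9,9.5,1817.5,1771.8
Schefflera abyssinica,5,11.12,1,0.9,47.4,0.9,51.6,1.2,127.9,145.8
Solanecio mannii,5,,0.8,1,53.3,3.5,46,4.2,8.6,4.6
Spermacoce princeae,5,11,79.8,14.6,12.5,7.8,7.7,7.7,98.6,38.4
Stachys aculeolata,13,,61,16.5,22.6,9.2,16.4,7.7,42.4,28.9
Stellaria mannii,14,,35.3,15.2,42.7,9.1,22,7.8,37,27
Tabernaemontana brachyantha,6,11.6,10.6,18.1,32,7.4,57.4,12.9,1894.5,1344.6
Tabernaemontana ventricosa,18,16.84,46.9,29.5,22.4,12.2,30.7,20.6,980.6,873.7
Thunbergia fasciculata,7,13.68,80.4,9.4,8.9,3.8,10.7,7.5,1271.1,2178.7
Trichilia rubescens,22,22.02,32,23,17.9,13.9,50.1,19.8,312.9,305.8
Voacanga africana,15,14.7,95,4.1,2.3,1.9,2.7,2.4,1239.4,575.8
Voacanga bracteata,12,16.69,80.4,21.5,10.6,13.6,8.9,8.3,2354,2817.9
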