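species,genus,family
Acanthonema strigosum,Acanthonema,Gesneriaceae
Acanthopale decempedalis,Acanthopale,Acanthaceae
Aframomum sp. purple,Aframomum,Zingiberaceae
Argocoffeopsis afzelii,Argocoffeopsis,Rubiaceae
Baccharoides calvoana,Baccharoides,Asteraceae
Bertiera racemosa,Bertiera,Rubiaceae
Brillantaisia owariensis,Brillantaisia,Acanthaceae
Calochone acuminata,Calochone,Rubiaceae
Chlorophytum comosum,Chlorophytum,Asparagaceae
Clematis simensis,Clematis,Ranunculaceae
Clerodendrum silvanum,Clerodendrum,Lamiaceae
Costus dubius,Costus,Costaceae
Crassocephalum montuosum,Crassocephalum,Asteraceae
Cuviera longiflora,Cuviera,Rubiaceae
Deinbollia sp. 1,Deinbollia,Sapindaceae
Dicranolepis vestita,Dicranolepis,Thymelaeaceae
Dioscoreophyllum cumminsii,Dioscoreophyllum,Menispermaceae
Dischistocalyx strobilinus,Dischistocalyx,Acanthaceae
Discoclaoxylon hexandrum,Discoclaoxylon,Euphorbiaceae
Discopodium penninervium,Discopodium,Solanaceae
Distephanus biafrae,Distephanus,Asteraceae
Gomphia flava,Gomphia,Ochnaceae
Heckeldora staudtii,Heckeldora,Meliaceae
Heinsia crinita,Heinsia,Rubiaceae
Hypoestes triflora,Hypoestes,Acanthaceae
Ilex mitis,Ilex,Aquifoliaceae
Impatiens burtonii,Impatiens,Balsaminaceae
Impatiens frithii,Impatiens,Balsaminaceae
Impatiens hians,Impatiens,Balsaminaceae
Impatiens macroptera,Impatiens,Balsaminaceae
Impatiens mannii,Impatiens,Balsaminaceae
Impatiens niamniamensis,Impatiens,Balsaminaceae
Impatiens sakeriana,Impatiens,Balsaminaceae
Isodon ramosissimus,Isodon,Lamiaceae
Isoglossa glandulifera,Isoglossa,Acanthaceae
Ixora foliosa,Ixora,Rubiaceae
Ixora guineensis,Ixora,Rubiaceae
Laccodiscus ferrugineus,Laccodiscus,Sapindaceae
Melanthera scandens,Melanthera,Asteraceae
Mikania cordata,Mikania,Asteraceae
Nuxia congesta,Nuxia,Stilbaceae
Oncoba dentata,Oncoba,Salicaceae
Pavetta hookeriana,Pavetta,Rubiaceae
Pavetta neurocarpa,Pavetta,Rubiaceae
Pavetta rigida,Pavetta,Rubiaceae
Plectranthus decurrens,Plectranthus,Lamiaceae
Plectranthus glandulosus,Plectranthus,Lamiaceae
Plectranthus kamerunensis,Plectranthus,Lamiaceae
Psychotria bifaria,Psychotria,Rubiaceae
Psychotria leptophylla,Psychotria,Rubiaceae
Psychotria peduncularis,Psychotria,Rubiaceae
Psychotria thonneri,Psychotria,Rubiaceae
Psydrax dunlapii,Psydrax,Rubiaceae
Sabicea calycina,Sabicea,Rubiaceae
Sabicea pilosa,Sabicea,Rubiaceae
Schefflera abyssinica,Schefflera,Araliaceae
Solanecio mannii,Solanecio,Asteraceae
Spermacoce princeae,Spermacoce,Rubiaceae
Stachys aculeolata,Stachys,Lamiaceae
Stellaria mannii,Stellaria,Caryophyllaceae
Tabernaemontana brachyantha,Tabernaemontana,Apocynaceae
Tabernaemontana ventricosa,Tabernaemontana,Apocynaceae
Thunbergia fasciculata,Thunbergia,Acanthaceae
Trichilia rubescens,Trichilia,Meliaceae
Voacanga africana,Voacanga,Apocynaceae
Voacanga bracteata,Voacanga,Apocynaceae
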