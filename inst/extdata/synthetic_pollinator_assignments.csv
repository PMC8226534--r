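species,primary_group
Acanthonema strigosum,bees
Acanthopale decempedalis,bees
Aframomum sp. purple,bees
Argocoffeopsis afzelii,bees
Baccharoides calvoana,butterflies
Bertiera racemosa,hoverflies
Brillantaisia owariensis,bees
Calochone acuminata,birds
Chlorophytum comosum,hoverflies
Clematis simensis,bees
Clerodendrum silvanum,butterflies
Costus dubius,birds
Crassocephalum montuosum,hoverflies
Cuviera longiflora,moths
Deinbollia sp. 1,bees
Dicranolepis vestita,moths
Dioscoreophyllum cumminsii,hoverflies
Dischistocalyx strobilinus,bees
Discoclaoxylon hexandrum,hoverflies
Discopodium penninervium,bees
Distephanus biafrae,butterflies
Gomphia flava,hoverflies
Heckeldora staudtii,moths
Heinsia crinita,butterflies
Hypoestes triflora,bees
Ilex mitis,bees
Impatiens burtonii,bees
Impatiens frithii,birds
Impatiens hians,birds
Impatiens macroptera,butterflies
Impatiens mannii,bees
Impatiens niamniamensis,birds
Impatiens sakeriana,birds
Isodon ramosissimus,bees
Isoglossa glandulifera,bees
Ixora foliosa,moths
Ixora guineensis,moths
Laccodiscus ferrugineus,bees
Melanthera scandens,butterflies
Mikania cordata,butterflies
Nuxia congesta,bees
Oncoba dentata,hoverflies
Pavetta hookeriana,butterflies
Pavetta neurocarpa,moths
Pavetta rigida,bees
Plectranthus decurrens,bees
Plectranthus glandulosus,bees
Plectranthus kamerunensis,bees
Psychotria bifaria,hoverflies
Psychotria leptophylla,hoverflies
Psychotria peduncularis,moths
Psychotria thonneri,moths
Psydrax dunlapii,moths
Sabicea calycina,birds
Sabicea pilosa,birds
Schefflera abyssinica,hoverflies
Solanecio mannii,hoverflies
Spermacoce princeae,moths
Stachys aculeolata,bees
Stellaria mannii,hoverflies
Tabernaemontana brachyantha,moths
Tabernaemontana ventricosa,moths
Thunbergia fasciculata,birds
Trichilia rubescens,bees
Voacanga africana,moths
Voacanga bracteata,birds
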