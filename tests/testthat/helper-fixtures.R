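# shared fixtures built in code

fixture_profiles <- function() {
  load_trait_table(nectar_example("mt_cameroon_nectar.csv"))
}

fixture_taxonomy <- function() {
  load_taxonomy(nectar_example("mt_cameroon_taxonomy.csv"))
}

three_tip_tree <- function() read_phylogeny("((A:1,B:1):1,C:2);")

balanced4 <- function() read_phylogeny("((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 8, depth = 1) {
  read_phylogeny(paste0("(", paste0("t", seq_len(n), ":", depth, collapse = ","),
                        ");"))
}
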