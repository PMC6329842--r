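# Independent brute-force oracle for the sum of sister-clade differences:
# a naive recursive evaluation, kept deliberately separate from the
# package's vectorised single-pass implementation.
oracle_sumd <- function(tree, trait) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  node_value <- function(node) {
    if (node <= n) return(as.numeric(trait[[tree$tip.label[node]]]))
    mean(vapply(children[[as.character(node)]], node_value, 0))
  }
  total <- 0
  for (i in seq_len(nrow(tree$edge))) {
    total <- total + abs(node_value(tree$edge[i, 1]) - node_value(tree$edge[i, 2]))
  }
  total
}

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

write_tree_text <- function(tr) ape::write.tree(tr)

star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  tr
}

# a tiny hand-built record table with known counts
toy_records <- function() {
  data.frame(
    study_id = c("S1", "S1", "S2", "S3", "S3", "S4", "S5"),
    species = c("Alouatta palliata", "Alouatta palliata", "Alouatta pigra",
                "Cebus capucinus", "Cebus capucinus", "Ateles geoffroyi",
                "Alouatta palliata"),
    family = c("Atelidae", "Atelidae", "Atelidae", "Cebidae", "Cebidae",
               "Atelidae", "Atelidae"),
    realm = rep("neotropics", 7),
    country = c("Mexico", "Mexico", "Belize", "Costa Rica", "Costa Rica",
                "Panama", "Mexico"),
    alc_type = c("secondary_forests", "secondary_forests", "open_areas",
                 "connectors", "connectors", "tree_plantations",
                 "human_settlements"),
    activity = c("foraging", "resting", "traveling", "foraging", "resting",
                 "", "all"),
    stringsAsFactors = FALSE
  )
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "alcuse")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", file)
  p
}

fixture_config <- function(out_dir, ...) {
  utils::modifyList(list(
    records = fixture_path("synthetic_records.csv"),
    traits = fixture_path("synthetic_world_traits.csv"),
    tree = fixture_path("synthetic_tree.nwk"),
    name_map = fixture_path("synthetic_name_map.csv"),
    out_dir = out_dir, seed = 42, permutations = 199,
    influence_replicates = 49, influence_permutations = 99
  ), list(...))
}
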