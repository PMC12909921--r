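## Species tree + nested clade chain.
##
## Age assignment needs (i) a rooted topology with named tips, (ii) an
## ordered chain of strictly nested clades running from the focal species out
## to the in-group root, and (iii) a set of excluded tips (distant outgroups
## dropped from presence/absence analysis because matches there are more
## plausibly re-introduction than descent).

#' Read a species tree with its nested clade chain
#'
#' @param path Newick file with named tips.
#' @param clade_config Either a path to a YAML file or a list, with elements
#'   `focal` (tip name), `steps` (ordered list of `name` + `species`, each
#'   step a strict superset of the previous; the first step must be the focal
#'   species alone) and optionally `excluded` (tips dropped from analysis).
#' @return An object of class `species_tree`: a list with `tree` (an
#'   [ape::read.tree()] phylo), `chain` (the validated step list), `focal`,
#'   and `excluded`.
#' @export
read_species_tree <- function(path, clade_config) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stopf("could not parse newick file %s", path)
  species_tree(tree, clade_config)
}

#' Construct a species tree object from an existing phylo
#'
#' @param tree An [ape::read.tree()] phylo object.
#' @inheritParams read_species_tree
#' @return A `species_tree` object; see [read_species_tree()].
#' @export
species_tree <- function(tree, clade_config) {
  cfg <- if (is.character(clade_config)) yaml::read_yaml(clade_config)
         else clade_config
  focal <- cfg$focal
  excluded <- as.character(cfg$excluded %||% character())
  steps <- lapply(cfg$steps, function(s)
    list(name = s$name, species = as.character(s$species)))
  if (is.null(focal) || !length(steps))
    stopf("clade config must supply 'focal' and 'steps'")
  tips <- tree$tip.label
  all_sp <- unique(unlist(lapply(steps, `[[`, "species")))
  miss <- setdiff(c(focal, all_sp, excluded), tips)
  if (length(miss))
    stopf("clade config names tip(s) absent from the tree: %s",
          paste(miss, collapse = ", "))
  if (!identical(steps[[1]]$species, focal))
    stopf("first chain step must be the focal species alone ('%s')", focal)
  for (i in seq_along(steps)) {
    s <- steps[[i]]$species
    if (i > 1L) {
      prev <- steps[[i - 1L]]$species
      if (!all(prev %in% s) || length(s) <= length(prev))
        stopf("chain step '%s' is not a strict superset of '%s'",
              steps[[i]]$name, steps[[i - 1L]]$name)
    }
    if (!is_monophyletic_set(tree, s))
      stopf("chain step '%s' is not monophyletic in the tree", steps[[i]]$name)
  }
  structure(list(tree = tree, chain = steps, focal = focal,
                 excluded = excluded),
            class = "species_tree")
}

is_monophyletic_set <- function(tree, species) {
  if (length(species) <= 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, species)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  setequal(clade_tips, species)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d tips, focal = %s, %d chain steps, %d excluded\n",
              length(x$tree$tip.label), x$focal, length(x$chain),
              length(x$excluded)))
  for (s in x$chain)
    cat(sprintf("  %-18s {%s}\n", s$name, paste(s$species, collapse = ", ")))
  invisible(x)
}

## Incremental "rings": species added at each chain step. Ring 1 is the focal
## species; the outermost ring is the deepest in-group addition.
chain_rings <- function(stree) {
  steps <- stree$chain
  rings <- vector("list", length(steps))
  rings[[1]] <- steps[[1]]$species
  for (i in seq_along(steps)[-1])
    rings[[i]] <- setdiff(steps[[i]]$species, steps[[i - 1]]$species)
  names(rings) <- vapply(steps, `[[`, character(1), "name")
  rings
}

#' Default termite phylogeny used by the simulator
#'
#' Eight tips: six in-group termites (*M. bellicosus*, *O.* sp2,
#' *T. geminatus*, *R. grassei*, *C. secundus*, *Z. nevadensis*) plus the two
#' distant outgroups *M. darwiniensis* and *C. punctulatus*, with branch
#' lengths in My on an ultrametric ladder (splits at 20, 50, 80, 130, 140,
#' 160 and 180 My before present).
#'
#' @return A newick string.
#' @export
termite_newick <- function() {
  paste0("(C_punctulatus:180,(M_darwiniensis:160,(Z_nevadensis:140,",
         "(C_secundus:130,(R_grassei:80,(T_geminatus:50,",
         "(O_sp2:20,M_bellicosus:20):30):30):50):10):20):20);")
}

#' Default termite clade-chain configuration
#'
#' The nested chain used for TE age groups, focal species *M. bellicosus*:
#' focal, Macrotermitinae, Termitidae, Geoisoptera, ancient (reaching either
#' *C. secundus* or *Z. nevadensis*); *M. darwiniensis* and *C. punctulatus*
#' are excluded from presence/absence analysis.
#'
#' @return A clade-config list accepted by [species_tree()].
#' @export
termite_clade_chain <- function() {
  list(
    focal = "M_bellicosus",
    steps = list(
      list(name = "M_bellicosus", species = "M_bellicosus"),
      list(name = "Macrotermitinae", species = c("M_bellicosus", "O_sp2")),
      list(name = "Termitidae",
           species = c("M_bellicosus", "O_sp2", "T_geminatus")),
      list(name = "Geoisoptera",
           species = c("M_bellicosus", "O_sp2", "T_geminatus", "R_grassei")),
      list(name = "ancient",
           species = c("M_bellicosus", "O_sp2", "T_geminatus", "R_grassei",
                       "C_secundus", "Z_nevadensis"))),
    excluded = c("M_darwiniensis", "C_punctulatus"))
}

#' Default species tree for the synthetic termite cohort
#'
#' @return A `species_tree` combining [termite_newick()] and
#'   [termite_clade_chain()].
#' @export
termite_species_tree <- function() {
  species_tree(ape::read.tree(text = termite_newick()), termite_clade_chain())
}
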