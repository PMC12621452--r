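# Frozen taxonomy vocabulary: 21 species groups, 9 taxonomic groups, 3 broad
# groups. The assignment mirrors the conventions of the uFISH market-group
# tables (sole and tilapia sit under "cichlid"; cod is its own group) even
# where biologically debatable, so that price joins line up.

.SPECIES_TAXON <- c(
  crab         = "crustacean",
  crayfish     = "crustacean",
  lobster      = "crustacean",
  shrimp_prawn = "crustacean",
  mackerel     = "small_pelagic",
  sole         = "cichlid",
  tilapia      = "cichlid",
  bass         = "demersal",
  catfish      = "demersal",
  pike         = "demersal",
  cod          = "cod",
  salmon       = "salmonid",
  trout        = "salmonid",
  clam         = "bivalve",
  mussel       = "bivalve",
  oyster       = "bivalve",
  scallop      = "bivalve",
  abalone      = "gastropod",
  conch        = "gastropod",
  octopus      = "cephalopod",
  squid        = "cephalopod"
)

.TAXON_BROAD <- c(
  crustacean    = "crustacean",
  small_pelagic = "finfish",
  cichlid       = "finfish",
  demersal      = "finfish",
  cod           = "finfish",
  salmonid      = "finfish",
  bivalve       = "mollusk",
  gastropod     = "mollusk",
  cephalopod    = "mollusk"
)

.BROAD_GROUPS <- c("crustacean", "finfish", "mollusk")
.TAXON_GROUPS <- names(.TAXON_BROAD)
.SPECIES_GROUPS <- names(.SPECIES_TAXON)
.STATES <- c("raw", "cooked", "preserved")
.HABITATS <- c("farmed", "wild", "unknown")
.SALINITIES <- c("freshwater", "saltwater", "unknown")

#' Species-group vocabulary
#'
#' @return Character vector of the 21 recognised species-group labels.
#' @export
species_groups <- function() .SPECIES_GROUPS

#' Taxonomic-group vocabulary
#'
#' @return Character vector of the 9 taxonomic group labels.
#' @export
taxon_groups <- function() .TAXON_GROUPS

#' Map a species group to its taxonomic and broad group
#'
#' Deterministic, frozen lookup over the 21-species vocabulary: for example
#' `mussel` maps to the bivalve mollusks and `mackerel` to the small pelagic
#' finfish. Vectorised over `species_group`.
#'
#' @param species_group Character vector of species-group labels.
#' @return A data frame with columns `species_group`, `taxon_group`,
#'   `broad_group`, one row per input label.
#' @export
#' @examples
#' species_to_taxon(c("mussel", "mackerel", "sole"))
species_to_taxon <- function(species_group) {
  species_group <- as.character(species_group)
  bad <- setdiff(unique(species_group), .SPECIES_GROUPS)
  if (length(bad) > 0) {
    stop(
      "unknown species_group label(s): ", paste(bad, collapse = ", "),
      ". Allowed labels: ", paste(.SPECIES_GROUPS, collapse = ", "),
      call. = FALSE
    )
  }
  taxon <- unname(.SPECIES_TAXON[species_group])
  data.frame(
    species_group = species_group,
    taxon_group = taxon,
    broad_group = unname(.TAXON_BROAD[taxon]),
    stringsAsFactors = FALSE
  )
}

match_vocab <- function(x, vocab, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) > 0) {
    stop(
      "unknown ", what, " label(s): ", paste(bad, collapse = ", "),
      ". Allowed: ", paste(vocab, collapse = ", "),
      call. = FALSE
    )
  }
  x
}
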