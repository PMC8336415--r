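CLADES <- c("Laurasiatheria", "Euarchontoglires", "Afrotheria", "Metatheria")

#' Build a species table
#'
#' @param species_id unique short species names.
#' @param clade one of Laurasiatheria, Euarchontoglires, Afrotheria
#'   (Eutherian clades) or Metatheria per species. Lineage (Eutheria or
#'   Metatheria) is derived from the clade.
#' @return data.frame with columns `species_id`, `clade`, `lineage`.
#' @export
species_table <- function(species_id, clade) {
  species_id <- as.character(species_id)
  clade <- as.character(clade)
  if (anyDuplicated(species_id)) abort("species_id values must be unique")
  bad <- setdiff(unique(clade), CLADES)
  if (length(bad) > 0) abort("unknown clade(s): %s", paste(bad, collapse = ", "))
  data.frame(species_id = species_id, clade = clade,
             lineage = ifelse(clade == "Metatheria", "Metatheria", "Eutheria"),
             stringsAsFactors = FALSE)
}

#' The 16-mammal study design
#'
#' Twelve Eutheria (four per clade: Laurasiatheria, Euarchontoglires,
#' Afrotheria) and four Metatheria, the marsupials for which genome data
#' are available.
#'
#' @return a species table, see [species_table()].
#' @export
mammal_species_table <- function() {
  species_table(
    species_id = c("sus_scrofa", "equus_asinus", "orcinus_orca", "felis_catus",
                   "cricetulus_griseus", "rattus_norvegicus",
                   "oryctolagus_cuniculus", "callithrix_jacchus",
                   "trichechus_manatus", "loxodonta_africana",
                   "chrysochloris_asiatica", "orycteropus_afer",
                   "vombatus_ursinus", "sarcophilus_harrisii",
                   "phascolarctos_cinereus", "monodelphis_domestica"),
    clade = rep(CLADES, each = 4)
  )
}

#' Default between-clade divergence times (My)
#'
#' A fixed four-level ultrametric: 70 My within each Eutherian clade, 96 My
#' between Euarchontoglires and Laurasiatheria, 104 My for the Afrotheria
#' split, 158.5 My between Eutheria and Metatheria, 60 My within Metatheria.
#' The deep calibrations follow published timetree means; all values are
#' configurable.
#'
#' @return named list of times in My.
#' @export
default_divergence_times <- function() {
  list(within_clade = 70, within_metatheria = 60,
       boreoeutheria = 96, afrotheria_split = 104,
       eutheria_metatheria = 158.5)
}

divergence_time <- function(clade_a, clade_b, times) {
  if (clade_a == clade_b) {
    return(if (clade_a == "Metatheria") times$within_metatheria else times$within_clade)
  }
  lin_a <- if (clade_a == "Metatheria") "M" else "E"
  lin_b <- if (clade_b == "Metatheria") "M" else "E"
  if (lin_a != lin_b) return(times$eutheria_metatheria)
  if (clade_a == "Afrotheria" || clade_b == "Afrotheria") return(times$afrotheria_split)
  times$boreoeutheria
}

#' All unordered species pairs with divergence times
#'
#' For S species there are choose(S, 2) pairs; 16 species make 120. Each pair
#' is classified as intra-Eutherian, Eutherian-Metatherian or
#' intra-Metatherian from the two lineages.
#'
#' @param species a [species_table()].
#' @param times named list as in [default_divergence_times()], or a symmetric
#'   numeric matrix of times (My) with species ids as dimnames.
#' @return data.frame with columns `pair_id`, `species_a`, `species_b`,
#'   `pair_class`, `t`.
#' @export
make_pair_table <- function(species, times = default_divergence_times()) {
  stopifnot(is.data.frame(species), nrow(species) >= 2)
  cmb <- utils::combn(nrow(species), 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  lin_a <- species$lineage[a]; lin_b <- species$lineage[b]
  pair_class <- ifelse(lin_a != lin_b, "Eutherian-Metatherian",
                       ifelse(lin_a == "Eutheria", "intra-Eutherian",
                              "intra-Metatherian"))
  if (is.matrix(times)) {
    t_val <- times[cbind(species$species_id[a], species$species_id[b])]
  } else {
    t_val <- mapply(divergence_time, species$clade[a], species$clade[b],
                    MoreArgs = list(times = times))
  }
  if (any(!is.finite(t_val)) || any(t_val <= 0)) {
    abort("all divergence times must be finite and > 0")
  }
  data.frame(pair_id = seq_along(a),
             species_a = species$species_id[a],
             species_b = species$species_id[b],
             pair_class = pair_class, t = as.numeric(t_val),
             stringsAsFactors = FALSE)
}

#' @rdname make_pair_table
#' @param path TSV path with the pair-table columns.
#' @export
read_pair_table <- function(path) {
  df <- read_tsv_strict(path, required = c("pair_id", "species_a", "species_b",
                                           "pair_class", "t"))
  df$t <- as.numeric(df$t)
  if (any(df$t <= 0)) abort("%s: divergence times must be > 0", path)
  df
}

#' @rdname make_pair_table
#' @param pairs a pair table to write.
#' @export
write_pair_table <- function(pairs, path) write_tsv(pairs, path)

#' @rdname species_table
#' @param path TSV path with columns `species_id`, `clade`.
#' @export
read_species_table <- function(path) {
  df <- read_tsv_strict(path, required = c("species_id", "clade"))
  species_table(df$species_id, df$clade)
}

#' @rdname species_table
#' @param species a species table to write.
#' @export
write_species_table <- function(species, path) write_tsv(species, path)
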