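#' @name mock_model
#' @title Expected 16S copy model for an even genomic-mass mock community
#'
#' @description
#' An even genomic-mass mock mixes equal DNA mass per member species, so the
#' number of genome copies each species contributes scales inversely with its
#' genome mass, and the number of 16S rDNA copies it contributes is that
#' genome copy number times its per-genome 16S copy count. The chain is:
#'
#' \deqn{GMW_i = L_i \times 607.4 \quad [g/mol]}
#' \deqn{nGM_i = GMW_i / N_A \times 10^9 \quad [ng]}
#' \deqn{m = c \times V / S \quad [ng\ per\ species]}
#' \deqn{GCN_i = m / nGM_i}
#' \deqn{E_i = GCN_i \times k_i, \qquad RA_i = E_i / \sum_j E_j}
#'
#' with \eqn{L_i} the genome length (bp), 607.4 g/mol the average weight of a
#' double-stranded base pair, \eqn{N_A} Avogadro's number, \eqn{c} the mix
#' concentration (ng/uL), \eqn{V} its volume (uL), \eqn{S} the number of
#' species and \eqn{k_i} the per-genome 16S copy number. Because the mass and
#' weight constants cancel in the ratio, \eqn{RA_i \propto k_i / L_i}.
NULL

#' Average molecular weight of one double-stranded base pair (g/mol).
#' @export
BP_WEIGHT <- 607.4

#' Avogadro's number (1/mol).
#' @export
AVOGADRO <- 6.022e23

#' Genome molecular weight from genome length
#'
#' @param length_bp Genome length in base pairs (nonnegative).
#' @return Molecular weight in g/mol (`length_bp * 607.4`).
#' @export
genome_molecular_weight <- function(length_bp) {
  if (any(length_bp < 0)) stop("genome length must be nonnegative")
  length_bp * BP_WEIGHT
}

#' Mass of a single genome copy in nanograms
#'
#' @param gmw Genome molecular weight in g/mol.
#' @return Mass of one genome copy in ng (`gmw / AVOGADRO * 1e9`).
#' @export
genome_mass_ng <- function(gmw) {
  if (any(gmw < 0)) stop("molecular weight must be nonnegative")
  gmw / AVOGADRO * 1e9
}

#' DNA mass allotted to each species in an even mix
#'
#' @param concentration Mix DNA concentration in ng/uL.
#' @param volume Mix volume in uL.
#' @param n_species Number of species sharing the mass evenly.
#' @return Per-species mass in ng (`concentration * volume / n_species`).
#' @export
per_species_mass <- function(concentration, volume, n_species) {
  if (any(concentration <= 0) || any(volume <= 0)) {
    stop("concentration and volume must be positive")
  }
  if (any(n_species < 1)) stop("n_species must be a positive integer")
  concentration * volume / n_species
}

#' Genome copy number within a given DNA mass
#'
#' @param mock_mass DNA mass available to the species, ng.
#' @param ngm Mass of one genome copy, ng.
#' @return Real-valued genome copy number (`mock_mass / ngm`); deliberately
#'   not rounded — only ratios matter downstream.
#' @export
genome_copy_number <- function(mock_mass, ngm) {
  if (any(ngm <= 0)) stop("per-genome mass must be positive")
  mock_mass / ngm
}

#' Expected 16S copy profile of an even genomic-mass mock community
#'
#' Chains the genome-weight, genome-mass, per-species-mass, genome-copy and
#' 16S-copy steps for every mock member and normalizes to relative
#' abundances. The relative abundances are invariant to `concentration`,
#' `volume` and the base-pair weight constant (they cancel) and satisfy
#' `expected_ra ~ ssu_copies / genome_length_bp`.
#'
#' @param species data.frame with columns `species`, `genome_length_bp`,
#'   `ssu_copies` (as read by [read_mock_metadata()]).
#' @param concentration Mix concentration in ng/uL.
#' @param volume Mix volume in uL.
#' @return data.frame of class `expected_profile` with columns `species`,
#'   `gmw_g_per_mol`, `ngm_ng`, `gcn`, `expected_16s_copies`, `expected_ra`.
#' @examples
#' mock <- data.frame(species = c("A", "B"),
#'                    genome_length_bp = c(2e6, 4e6), ssu_copies = c(4, 4))
#' expected_profile(mock)
#' @export
expected_profile <- function(species, concentration = 2.6, volume = 50) {
  if (!nrow(species)) stop("species list must be nonempty")
  need <- c("species", "genome_length_bp", "ssu_copies")
  if (!all(need %in% names(species))) {
    stop("species table must contain: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(species$species)) stop("duplicate species names")
  if (any(species$genome_length_bp < 1) || any(species$ssu_copies < 1)) {
    stop("genome_length_bp and ssu_copies must be >= 1")
  }
  gmw <- genome_molecular_weight(species$genome_length_bp)
  ngm <- genome_mass_ng(gmw)
  mass <- per_species_mass(concentration, volume, nrow(species))
  gcn <- genome_copy_number(mass, ngm)
  copies <- gcn * species$ssu_copies
  out <- data.frame(species = species$species,
                    gmw_g_per_mol = gmw, ngm_ng = ngm, gcn = gcn,
                    expected_16s_copies = copies,
                    expected_ra = copies / sum(copies),
                    stringsAsFactors = FALSE)
  class(out) <- c("expected_profile", "data.frame")
  out
}

#' @export
print.expected_profile <- function(x, ...) {
  cat("Expected 16S copy profile (", nrow(x), " species)\n", sep = "")
  df <- as.data.frame(x)
  df$expected_ra <- sprintf("%.4f", df$expected_ra)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Collapse an expected profile to a coarser taxonomic rank
#'
#' Relative abundances of members sharing a label are summed; used e.g. to
#' compare genus-level observations against a species-level mock design.
#'
#' @param profile An `expected_profile`.
#' @param labels Character vector (one per profile row) of rank labels.
#' @return data.frame with columns `taxon` and `expected_ra`.
#' @export
collapse_profile <- function(profile, labels) {
  stopifnot(length(labels) == nrow(profile))
  agg <- stats::aggregate(list(expected_ra = profile$expected_ra),
                          by = list(taxon = labels), FUN = sum)
  agg[order(agg$taxon), , drop = FALSE]
}
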