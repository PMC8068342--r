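#' Radical-scavenger (DMSO) survival parameters
#'
#' Parameter bundle for the hyperbolic per-lesion survival model under a
#' hydroxyl-radical scavenger: `fnsd` is the fraction of non-scavengeable
#' damage (the survival floor at saturating scavenger) and `chmx` is the
#' concentration at which the scavengeable component is halved.
#'
#' @param fnsd fraction of non-scavengeable damage, in (0, 1].
#' @param chmx half-effect concentration in mol/L, > 0.
#' @return An object of class `scavenger_params`.
#' @seealso [dmso_survival_factor()], [scavenger_preset()]
#' @export
#' @examples
#' scavenger_params(fnsd = 0.52, chmx = 0.07)
scavenger_params <- function(fnsd, chmx) {
  check_number(fnsd, "fnsd", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(chmx, "chmx", lower = 0, strict_lower = TRUE)
  structure(list(fnsd = fnsd, chmx = chmx), class = "scavenger_params")
}

#' @export
print.scavenger_params <- function(x, ...) {
  cat(sprintf("Scavenger parameters: FNSD = %.3g, CHMX = %.3g M\n",
              x$fnsd, x$chmx))
  invisible(x)
}

#' Built-in scavenger parameter presets
#'
#' Published (FNSD, CHMX) pairs for the three radiation qualities handled by
#' the package: 60Co gamma-rays (0.52, 0.21 M), 62 MeV protons
#' (0.52, 0.07 M) and 3.31 MeV helium ions (0.75, 0.14 M).
#'
#' @param name one of `"cobalt60"`, `"proton62MeV"`, `"helium3.31MeV"`.
#' @return A [scavenger_params()] object.
#' @export
scavenger_preset <- function(name = c("cobalt60", "proton62MeV", "helium3.31MeV")) {
  name <- match.arg(name)
  switch(name,
    cobalt60       = scavenger_params(0.52, 0.21),
    proton62MeV    = scavenger_params(0.52, 0.07),
    `helium3.31MeV` = scavenger_params(0.75, 0.14))
}

#' Oxygen-effect survival parameters
#'
#' Parameters of the hyperbolic (Alper--Howard-Flanders form) lesion-level
#' oxygen modification factor `h(x) = (m * x + k) / (x + k)`, normalised to
#' 1 at the aerobic reference tension (21% O2 by default).  `m_lesion` is
#' the maximal lesion-level enhancement at full oxygenation relative to
#' anoxia; `k_o2` is the tension (% O2) at half effect.
#'
#' @param m_lesion maximal lesion-level modification, >= 1.
#' @param k_o2 half-effect oxygen tension in % O2, > 0.
#' @param reference_o2 tension at which the survival factor equals 1.
#' @return An object of class `oxygen_params`.
#' @seealso [oxygen_survival_factor()], [calibrate_oxygen()]
#' @export
oxygen_params <- function(m_lesion = 1.75, k_o2 = 0.7, reference_o2 = 21) {
  check_number(m_lesion, "m_lesion", lower = 1)
  check_number(k_o2, "k_o2", lower = 0, strict_lower = TRUE)
  check_number(reference_o2, "reference_o2", lower = 0, upper = 100,
               strict_lower = TRUE)
  structure(list(m_lesion = m_lesion, k_o2 = k_o2,
                 reference_o2 = reference_o2), class = "oxygen_params")
}

#' @export
print.oxygen_params <- function(x, ...) {
  cat(sprintf(
    "Oxygen parameters: m = %.4g, K = %.4g%% O2 (reference %.3g%% O2)\n",
    x$m_lesion, x$k_o2, x$reference_o2))
  invisible(x)
}

#' Environmental condition (DMSO concentration and oxygen tension)
#'
#' @param dmso_M DMSO concentration in mol/L, >= 0.
#' @param o2_percent oxygen tension in %, between 0 and 100.
#' @return An object of class `environment_condition`.
#' @export
#' @examples
#' environment_condition(dmso_M = 0.1, o2_percent = 2)
environment_condition <- function(dmso_M = 0, o2_percent = 21) {
  check_number(dmso_M, "dmso_M", lower = 0)
  check_number(o2_percent, "o2_percent", lower = 0, upper = 100)
  structure(list(dmso_M = dmso_M, o2_percent = o2_percent),
            class = "environment_condition")
}

#' @export
print.environment_condition <- function(x, ...) {
  cat(sprintf("Condition: %.3g M DMSO, %.4g%% O2\n", x$dmso_M, x$o2_percent))
  invisible(x)
}

#' Radiation quality
#'
#' Bundles the cluster-generation parameters of one radiation quality with
#' its scavenger and oxygen survival parameters.  `cluster_rate_rho` is the
#' mean number of damage clusters per Gy per Gbp; `multiplicity_nu` the mean
#' extra-lesion count per cluster (each cluster carries `1 + Poisson(nu)`
#' lesions); `p_strand_break` the per-lesion probability of being a strand
#' break rather than a base damage; and `nseg` the DNA segment length (bp)
#' over which a cluster's lesions are scattered.
#'
#' @param name label for output tables.
#' @param let_keV_um nominal LET in keV/um (label only; not used in the
#'   sampling model).
#' @param cluster_rate_rho clusters per Gy per Gbp, > 0.
#' @param multiplicity_nu mean extra lesions per cluster, >= 0.
#' @param p_strand_break probability a lesion is a strand break, in (0, 1).
#' @param nseg segment length in bp, > 10.
#' @param scavenger a [scavenger_params()] object.
#' @param oxygen an [oxygen_params()] object.
#' @return An object of class `radiation_quality`.
#' @export
radiation_quality <- function(name, let_keV_um, cluster_rate_rho,
                              multiplicity_nu, p_strand_break, nseg,
                              scavenger = scavenger_preset("cobalt60"),
                              oxygen = oxygen_params()) {
  stopifnot(is.character(name), length(name) == 1L)
  check_number(let_keV_um, "let_keV_um", lower = 0)
  check_number(cluster_rate_rho, "cluster_rate_rho", lower = 0, strict_lower = TRUE)
  check_number(multiplicity_nu, "multiplicity_nu", lower = 0)
  check_number(p_strand_break, "p_strand_break", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(nseg, "nseg", lower = 10, strict_lower = TRUE)
  if (!inherits(scavenger, "scavenger_params")) stopf("'scavenger' must be scavenger_params")
  if (!inherits(oxygen, "oxygen_params")) stopf("'oxygen' must be oxygen_params")
  structure(list(name = name, let_keV_um = let_keV_um,
                 cluster_rate_rho = cluster_rate_rho,
                 multiplicity_nu = multiplicity_nu,
                 p_strand_break = p_strand_break,
                 nseg = as.integer(round(nseg)),
                 scavenger = scavenger, oxygen = oxygen),
            class = "radiation_quality")
}

#' @export
print.radiation_quality <- function(x, ...) {
  cat(sprintf("Radiation quality '%s' (LET %.4g keV/um)\n", x$name, x$let_keV_um))
  cat(sprintf("  cluster rate rho : %.4g per Gy per Gbp\n", x$cluster_rate_rho))
  cat(sprintf("  multiplicity nu  : %.4g extra lesions/cluster\n", x$multiplicity_nu))
  cat(sprintf("  P(strand break)  : %.4g\n", x$p_strand_break))
  cat(sprintf("  segment length   : %d bp\n", x$nseg))
  print(x$scavenger); print(x$oxygen)
  invisible(x)
}

#' Simulation configuration
#'
#' Controls dose, simulated genome size and reproducibility of a Monte
#' Carlo damage run.  Either `genome_gbp` (Poisson cluster count with mean
#' `rho * dose * genome_gbp`) or `n_clusters` (fixed-count mode; the
#' dose-normalising genome equivalent `n_clusters / (rho * dose)` is
#' recorded in run metadata) must be given.
#'
#' @param dose absorbed dose in Gy, > 0.
#' @param genome_gbp simulated genome size in Gbp (Poisson-count mode).
#' @param n_clusters fixed number of clusters to simulate (fixed-count mode).
#' @param per_cell_factor Gbp per cell used for per-cell conversions
#'   (default 6 Gbp for a typical mammalian cell).
#' @param seed integer RNG seed for the run.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dose = 1, genome_gbp = NULL, n_clusters = NULL,
                              per_cell_factor = 6, seed = 1L) {
  check_number(dose, "dose", lower = 0, strict_lower = TRUE)
  check_number(per_cell_factor, "per_cell_factor", lower = 0, strict_lower = TRUE)
  if (is.null(genome_gbp) == is.null(n_clusters))
    stopf("give exactly one of 'genome_gbp' or 'n_clusters'")
  if (!is.null(genome_gbp))
    check_number(genome_gbp, "genome_gbp", lower = 0, strict_lower = TRUE)
  if (!is.null(n_clusters))
    check_number(n_clusters, "n_clusters", lower = 1)
  structure(list(dose = dose, genome_gbp = genome_gbp,
                 n_clusters = if (!is.null(n_clusters)) as.integer(n_clusters),
                 per_cell_factor = per_cell_factor,
                 seed = as.integer(seed)),
            class = "simulation_config")
}
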