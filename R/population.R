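#' Lesion population (a collection of damage clusters)
#'
#' Column-oriented container for a population of damage clusters.  Each
#' lesion carries its owning cluster index, its base-pair offset within the
#' cluster's segment, its strand (0/1) and its kind (strand break or base
#' damage).  Lesions are stored sorted by cluster and then by position;
#' `n_clusters` counts all clusters ever generated, including any that have
#' become empty through thinning (empty clusters are classified `EMPTY` and
#' excluded from yields).
#'
#' @param cluster integer vector of cluster indices (1-based).
#' @param position integer base-pair offsets, `0 <= position < nseg`.
#' @param strand integer vector of 0/1 strand labels.
#' @param is_break logical; `TRUE` for a strand break, `FALSE` for base damage.
#' @param n_clusters total number of clusters represented.
#' @param nseg segment length (bp) shared by all clusters.
#' @param meta optional list of run metadata.
#' @return An object of class `lesion_population`.
#' @export
lesion_population <- function(cluster, position, strand, is_break,
                              n_clusters, nseg, meta = list()) {
  n_clusters <- as.integer(n_clusters)
  cluster <- as.integer(cluster); position <- as.integer(position)
  strand <- as.integer(strand); is_break <- as.logical(is_break)
  L <- length(cluster)
  if (length(position) != L || length(strand) != L || length(is_break) != L)
    stopf("lesion fields must have equal length")
  if (L) {
    if (min(position) < 0L || max(position) >= nseg)
      stopf("positions must lie in [0, nseg)")
    if (!all(strand %in% c(0L, 1L))) stopf("strand must be 0 or 1")
    if (min(cluster) < 1L || max(cluster) > n_clusters)
      stopf("cluster indices out of range")
    o <- order(cluster, position)
    cluster <- cluster[o]; position <- position[o]
    strand <- strand[o]; is_break <- is_break[o]
  }
  structure(list(cluster = cluster, position = position, strand = strand,
                 is_break = is_break, n_clusters = n_clusters,
                 nseg = as.integer(nseg), meta = meta),
            class = "lesion_population")
}

#' @export
print.lesion_population <- function(x, ...) {
  L <- length(x$cluster)
  occ <- if (L) length(unique(x$cluster)) else 0L
  cat(sprintf("Lesion population: %d clusters (%d non-empty), %d lesions, nseg = %d bp\n",
              x$n_clusters, occ, L, x$nseg))
  if (L) {
    cat(sprintf("  strand breaks: %d, base damages: %d, mean lesions/non-empty cluster: %.3f\n",
                sum(x$is_break), sum(!x$is_break), L / occ))
  }
  if (!is.null(x$meta$survival))
    cat(sprintf("  per-lesion survival applied: %.4f\n", x$meta$survival))
  invisible(x)
}

#' Number of lesions in a population
#' @param pop a [lesion_population()].
#' @return integer lesion count.
#' @export
n_lesions <- function(pop) length(pop$cluster)

#' Generate track-induced lesion clusters
#'
#' Samples a population of damage clusters for one radiation quality.  The
#' number of clusters is Poisson with mean
#' `cluster_rate_rho * dose * genome_gbp`, or exactly `n_clusters` in
#' fixed-count mode (the equivalent genome size is then recorded in the
#' metadata and used for dose normalisation by [tally_yields()]).  Each
#' cluster receives `1 + Poisson(multiplicity_nu)` lesions with i.i.d.
#' uniform integer positions on `[0, nseg)`, fair-coin strands, and strand
#' breaks with probability `p_strand_break`.
#'
#' @param quality a [radiation_quality()].
#' @param config a [simulation_config()].
#' @param seed RNG seed; defaults to the seed in `config`.
#' @return A [lesion_population()].
#' @export
#' @examples
#' q <- radiation_quality("demo", 1, cluster_rate_rho = 100,
#'                        multiplicity_nu = 0.5, p_strand_break = 0.3, nseg = 25)
#' pop <- generate_clusters(q, simulation_config(genome_gbp = 0.01, seed = 2))
#' pop
generate_clusters <- function(quality, config, seed = NULL) {
  if (!inherits(quality, "radiation_quality")) stopf("'quality' must be a radiation_quality")
  if (!inherits(config, "simulation_config")) stopf("'config' must be a simulation_config")
  seed <- seed %||% config$seed
  with_seed(derive_seed(seed, "generate"), {
    if (is.null(config$n_clusters)) {
      mu <- quality$cluster_rate_rho * config$dose * config$genome_gbp
      n <- rpois(1L, mu)
      genome_gbp <- config$genome_gbp
    } else {
      n <- config$n_clusters
      genome_gbp <- n / (quality$cluster_rate_rho * config$dose)
    }
    if (n == 0L) {
      return(lesion_population(integer(), integer(), integer(), logical(),
                               0L, quality$nseg,
                               meta = list(quality = quality$name,
                                           dose = config$dose,
                                           genome_gbp = genome_gbp,
                                           fixed_count = !is.null(config$n_clusters),
                                           seed = seed)))
    }
    sizes <- 1L + rpois(n, quality$multiplicity_nu)
    L <- sum(sizes)
    cl <- rep.int(seq_len(n), sizes)
    pos <- sample.int(quality$nseg, L, replace = TRUE) - 1L
    strand <- sample.int(2L, L, replace = TRUE) - 1L
    brk <- runif(L) < quality$p_strand_break
    lesion_population(cl, pos, strand, brk, n, quality$nseg,
                      meta = list(quality = quality$name, dose = config$dose,
                                  genome_gbp = genome_gbp,
                                  fixed_count = !is.null(config$n_clusters),
                                  seed = seed))
  })
}

#' Build deterministic toy clusters from explicit lesion recipes
#'
#' Turns a list of explicit lesion tables into a [lesion_population()] for
#' unit testing of classification and repair.  Each recipe element is a
#' data frame (or list) with components `position`, `strand` and `kind`
#' (`"break"` or `"bd"`).
#'
#' @param recipe list of lesion tables, one per cluster; may be empty.
#' @param nseg segment length; defaults to 1 + the largest position (at
#'   least 11 so the segment-length invariant holds).
#' @return A [lesion_population()].
#' @export
#' @examples
#' make_toy_clusters(list(
#'   data.frame(position = c(100, 106), strand = c(0, 1),
#'              kind = c("break", "break"))), nseg = 200)
make_toy_clusters <- function(recipe, nseg = NULL) {
  if (!is.list(recipe)) stopf("'recipe' must be a list of lesion tables")
  if (!length(recipe)) {
    return(lesion_population(integer(), integer(), integer(), logical(),
                             0L, nseg %||% 11L))
  }
  parts <- lapply(seq_along(recipe), function(i) {
    r <- as.data.frame(recipe[[i]])
    if (!all(c("position", "strand", "kind") %in% names(r)))
      stopf("recipe element %d lacks position/strand/kind", i)
    if (!all(r$kind %in% c("break", "bd")))
      stopf("lesion kind must be 'break' or 'bd'")
    data.frame(cluster = i, position = as.integer(r$position),
               strand = as.integer(r$strand), is_break = r$kind == "break")
  })
  all <- do.call(rbind, parts)
  nseg <- nseg %||% max(11L, max(all$position) + 1L)
  lesion_population(all$cluster, all$position, all$strand, all$is_break,
                    length(recipe), nseg)
}
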