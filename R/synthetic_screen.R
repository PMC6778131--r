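#' Configuration for a simulated pooled CRISPR screen
#'
#' The generative model behind the screen readout: the realised library
#' composition is Dirichlet-distributed around the uniform design (per-guide
#' Gamma shape `1/plasmid_dispersion`); each guide carries a knockout
#' efficacy drawn once from a Beta distribution; the culture frequency of
#' guide i at day t is proportional to its library frequency times
#' `exp(efficacy_i * s_gene * t)`; and every sequenced sample (the plasmid
#' reference and each timepoint x replicate) is a multinomial draw of
#' `depth_per_sample` reads.
#'
#' @param fitness_map Named numeric vector, gene -> selection coefficient per
#'   day (0 = neutral). Genes absent from the map are neutral. The NTC
#'   pseudo-gene must be neutral.
#' @param guide_efficacy_shape Two-element `c(alpha, beta)` of the Beta
#'   distribution of per-guide knockout efficacy in \[0, 1\].
#' @param plasmid_dispersion Overdispersion of the realised library around
#'   the uniform design; per-guide Gamma shape is `1/plasmid_dispersion`,
#'   so 0 means an exactly uniform library.
#' @param depth_per_sample Reads per sequenced sample.
#' @param timepoints Character day labels such as `"d21"`; the numeric part
#'   is the time in days used by the selection model.
#' @param n_replicates Number of culture replicates per timepoint.
#' @param seed Integer seed.
#' @param ntc_label NTC sentinel gene label.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(fitness_map = numeric(0),
                              guide_efficacy_shape = c(8, 2),
                              plasmid_dispersion = 0.1,
                              depth_per_sample = 6e6,
                              timepoints = c("d21", "d70"),
                              n_replicates = 3L,
                              seed = 1L,
                              ntc_label = "NTC") {
  if (depth_per_sample <= 0) stop("depth_per_sample must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (plasmid_dispersion < 0) stop("plasmid_dispersion must be >= 0")
  if (ntc_label %in% names(fitness_map) && fitness_map[[ntc_label]] != 0) {
    stop("the NTC pseudo-gene must have selection coefficient 0")
  }
  days <- parse_day_labels(timepoints)
  cfg <- list(
    fitness_map = fitness_map,
    guide_efficacy_shape = guide_efficacy_shape,
    plasmid_dispersion = plasmid_dispersion,
    depth_per_sample = depth_per_sample,
    timepoints = as.character(timepoints),
    days = days,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    ntc_label = ntc_label
  )
  class(cfg) <- "screen_sim_config"
  cfg
}

parse_day_labels <- function(labels) {
  days <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", labels)))
  if (any(is.na(days))) {
    stop("timepoint labels must contain a numeric day, e.g. 'd21': ",
         paste(labels[is.na(days)], collapse = ", "))
  }
  days
}

#' Simulate a pooled CRISPR screen
#'
#' Produces a guide x sample count matrix with one shared plasmid reference
#' sample and one sample per timepoint x replicate, under the selection model
#' documented in [screen_sim_config()].
#'
#' @param library A `guide_library` data frame.
#' @param config A [screen_sim_config()].
#' @return A `screen_counts` list with elements `counts` (integer matrix,
#'   guides x samples) and `samples` (data frame with
#'   `sample_id, timepoint, replicate, is_plasmid`).
#' @export
simulate_screen <- function(library, config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  genes <- unique(library$gene)
  unknown <- setdiff(names(config$fitness_map), genes)
  if (length(unknown) > 0) {
    stop("fitness_map names not in the library: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(config$seed)
  m <- nrow(library)

  s_gene <- setNames(rep(0, length(genes)), genes)
  s_gene[names(config$fitness_map)] <- config$fitness_map
  s_guide <- s_gene[library$gene]
  efficacy <- rbeta(m, config$guide_efficacy_shape[1], config$guide_efficacy_shape[2])
  # NTCs cut nothing; their realised effect is identically zero
  efficacy[library$is_ntc] <- 0

  if (config$plasmid_dispersion > 0) {
    p <- rgamma(m, shape = 1 / config$plasmid_dispersion, rate = 1)
    p <- p / sum(p)
  } else {
    p <- rep(1 / m, m)
  }

  samples <- data.frame(
    sample_id = "plasmid", timepoint = "plasmid", replicate = 0L,
    is_plasmid = TRUE, stringsAsFactors = FALSE
  )
  counts <- matrix(0L, nrow = m, ncol = 0)
  counts <- cbind(counts, rmultinom(1, config$depth_per_sample, p))

  for (ti in seq_along(config$timepoints)) {
    f <- p * exp(efficacy * s_guide * config$days[ti])
    f <- f / sum(f)
    for (r in seq_len(config$n_replicates)) {
      counts <- cbind(counts, rmultinom(1, config$depth_per_sample, f))
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_r%d", config$timepoints[ti], r),
        timepoint = config$timepoints[ti], replicate = r,
        is_plasmid = FALSE, stringsAsFactors = FALSE
      ))
    }
  }
  dimnames(counts) <- list(library$guide_id, samples$sample_id)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "screen_counts")
}

#' Planted-effect screen configuration
#'
#' The standard recovery experiment: a set of positively selected and a set of
#' negatively selected genes at symmetric per-day selection coefficients, all
#' other genes neutral.
#'
#' @param library A `guide_library`.
#' @param n_positive,n_negative Number of planted genes per direction.
#' @param s Absolute selection coefficient per day.
#' @param seed Integer seed (controls which genes are planted and the screen).
#' @param ... Further arguments passed to [screen_sim_config()].
#' @return List with elements `config` (a `screen_sim_config`), `positive`
#'   and `negative` (planted gene sets).
#' @export
planted_screen_config <- function(library, n_positive = 10, n_negative = 10,
                                  s = 0.3, seed = 1L, ...) {
  genes <- setdiff(unique(library$gene), "NTC")
  set.seed(seed)
  planted <- sample(genes, n_positive + n_negative)
  positive <- planted[seq_len(n_positive)]
  negative <- planted[n_positive + seq_len(n_negative)]
  fitness <- c(setNames(rep(s, n_positive), positive),
               setNames(rep(-s, n_negative), negative))
  list(
    config = screen_sim_config(fitness_map = fitness, seed = seed, ...),
    positive = positive,
    negative = negative
  )
}
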