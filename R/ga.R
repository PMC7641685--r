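#' GA configuration
#'
#' Defaults: population 30, 20 generations, tournament selection of size 3,
#' uniform crossover with rate 0.8, per-gene Gaussian mutation with standard
#' deviation 0.1 of the gene range (clipped to bounds), and elitism of 1.
#'
#' @param population,generations,tournament,elitism Integers.
#' @param crossover_rate Probability of uniform crossover (else the first
#'   parent is copied).
#' @param mutation_sd Mutation standard deviation as a fraction of each gene's
#'   range.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 30L, generations = 20L, tournament = 3L,
                      crossover_rate = 0.8, mutation_sd = 0.1, elitism = 1L,
                      seed = 1L) {
  if (population < 1L) stopf("population must be at least 1")
  if (generations < 1L) stopf("generations must be at least 1")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 crossover_rate = crossover_rate, mutation_sd = mutation_sd,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

gene_lower <- c(H = 1e-3, W = 1e-3, CutVal = 0)
gene_upper <- c(H = 1, W = 1, CutVal = 255)

#' Optimize an ROI chromosome with a genetic algorithm
#'
#' Maximizes `fitness` over the three-gene chromosome (`H`, `W`, `CutVal`).
#' The fitness callback is pluggable: the full pipeline fitness trains a
#' classifier and returns its AUOC, while [surrogate_lesion_fitness()] offers
#' a fast lesion-overlap score for phantom cohorts.
#'
#' @param fitness Function mapping a [chromosome()] to a numeric score
#'   (larger is better).
#' @param config A [ga_config()].
#' @return A list with `best` (the best [chromosome()]), `fitness` (its
#'   score) and `history` (best score per generation).
#' @export
ga_optimize <- function(fitness, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  lo <- gene_lower; hi <- gene_upper
  range <- hi - lo
  withr::with_seed(config$seed, {
    pop <- t(vapply(seq_len(config$population),
                    function(i) lo + runif(3) * range, numeric(3)))
    colnames(pop) <- names(lo)
    evaluate <- function(p)
      apply(p, 1L, function(g) fitness(chromosome(g[1], g[2], g[3])))
    fit <- evaluate(pop)
    best_idx <- which.max(fit)
    best <- pop[best_idx, ]; best_fit <- fit[best_idx]
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      nextpop <- matrix(NA_real_, config$population, 3L,
                        dimnames = list(NULL, names(lo)))
      n_elite <- min(config$elitism, config$population)
      if (n_elite > 0L)
        nextpop[seq_len(n_elite), ] <-
          pop[order(fit, decreasing = TRUE)[seq_len(n_elite)], , drop = FALSE]
      pick <- function() {
        cand <- sample.int(config$population, min(config$tournament,
                                                  config$population))
        pop[cand[which.max(fit[cand])], ]
      }
      for (i in seq.int(n_elite + 1L, length.out = config$population - n_elite)) {
        p1 <- pick(); p2 <- pick()
        child <- if (runif(1) < config$crossover_rate) {
          take <- runif(3) < 0.5
          ifelse(take, p1, p2)
        } else p1
        child <- child + rnorm(3, sd = config$mutation_sd * range)
        nextpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- nextpop
      fit <- evaluate(pop)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best <- pop[which.max(fit), ]
      }
      history[gen] <- best_fit
    }
    list(best = chromosome(best[["H"]], best[["W"]], best[["CutVal"]]),
         fitness = best_fit, history = history)
  })
}

#' Surrogate GA fitness: lesion overlap on a phantom cohort
#'
#' Precomputes the cleaned image and IROI for every abnormal phantom in the
#' cohort and returns a fitness closure scoring a chromosome by the fraction
#' of refined ROIs that contain the planted lesion center. Much faster than
#' the full train-and-score fitness, and available only where ground truth is
#' known.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param stride Placement stride passed to [refine_roi()].
#' @return A function `fitness(chrom)` returning a value in \[0, 1\].
#' @export
surrogate_lesion_fitness <- function(cohort, stride = 8L) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  abnormal <- which(cohort$metadata$class != "normal")
  if (length(abnormal) == 0L) stopf("cohort has no abnormal phantoms")
  prepared <- lapply(abnormal, function(i) {
    px <- cohort$records[[i]]$pixels
    side <- detect_side(px)
    cleaned <- remove_pectoral(remove_artifacts(px, side), side)
    list(cleaned = cleaned, iroi = initial_roi(cleaned),
         center = cohort$truth[[i]]$lesion_center)
  })
  function(chrom) {
    hits <- vapply(prepared, function(p) {
      roi <- refine_roi(p$cleaned, p$iroi, chrom, stride = stride)
      b <- roi$bounds
      r <- p$center[1] - 1; c <- p$center[2] - 1
      r >= b[["row0"]] && r < b[["row1"]] && c >= b[["col0"]] && c < b[["col1"]]
    }, logical(1))
    mean(hits)
  }
}
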