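# Generators for every input the pipeline consumes, with known ground
# truth.  Each generator is deterministic under its seed, echoes the seed
# into the output header (CSV comment line) and writes a machine-readable
# ground-truth sidecar (<path>.truth.json) when asked to write files;
# downstream recovery tests read truth only from the sidecar.

.write_truth <- function(path, truth) {
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate per-locality plate measurements
#'
#' Draws `n` areas per locality from Normal(mean_area, sd_area).  An
#' optional step decrease emulates a Lilliput response: localities strictly
#' younger than `event_shrink$age_ma` have their true mean multiplied by
#' `event_shrink$factor` before drawing.  Values are plain normal draws —
#' negative areas are possible and kept, matching the model the test
#' assumes.
#'
#' @param specs Data frame with columns `locality`, `age_ma`, `n`,
#'   `mean_area`, `sd_area`.
#' @param event_shrink Optional `list(age_ma =, factor =)` step change.
#' @param seed Integer seed.
#' @param path Optional CSV output path; the ground truth goes to
#'   `<path>.truth.json`.
#' @return The generated `assemblage_series` (invisibly when writing), with
#'   the effective per-locality true means attached as attribute `"truth"`.
#' @export
gen_assemblages <- function(specs, event_shrink = NULL, seed = 1L,
                            path = NULL) {
  need <- c("locality", "age_ma", "n", "mean_area", "sd_area")
  stopifnot(all(need %in% names(specs)))
  if (any(specs$n < 1L)) stop("every assemblage spec needs n >= 1")
  if (any(specs$sd_area < 0)) stop("sd_area must be >= 0")
  true_mean <- specs$mean_area
  if (!is.null(event_shrink)) {
    stopifnot(is.numeric(event_shrink$factor), event_shrink$factor > 0)
    true_mean <- ifelse(specs$age_ma < event_shrink$age_ma,
                        true_mean * event_shrink$factor, true_mean)
  }
  set.seed(seed)
  series <- assemblage_series(lapply(seq_len(nrow(specs)), function(i)
    assemblage(locality = as.character(specs$locality[i]),
               age_ma = specs$age_ma[i],
               areas = stats::rnorm(specs$n[i], true_mean[i],
                                    specs$sd_area[i]))))
  n_neg <- sum(vapply(series, function(a) sum(a$areas < 0), integer(1)))
  if (n_neg > 0)
    message("gen_assemblages: ", n_neg,
            " negative simulated area(s) kept (untruncated normal model)")
  truth <- list(seed = seed,
                locality = as.character(specs$locality),
                age_ma = specs$age_ma, n = specs$n,
                true_mean = true_mean, true_sd = specs$sd_area,
                event_shrink = event_shrink)
  attr(series, "truth") <- truth
  if (!is.null(path)) {
    rows <- do.call(rbind, lapply(series, function(a)
      data.frame(locality = a$locality, age_ma = a$age_ma, area = a$areas)))
    con <- file(path, "w")
    writeLines(paste0("# seed: ", seed), con)
    utils::write.csv(format(rows, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
    close(con)
    .write_truth(path, truth)
    return(invisible(series))
  }
  series
}

.stage_at <- function(stages, age) {
  # half-open [start_ma, end_ma): a boundary age belongs to the younger
  # stage except at the oldest boundary
  i <- which(age <= stages$start_ma & age > stages$end_ma)
  if (length(i) == 0L && age == stages$start_ma[1L]) i <- 1L
  i[1L]
}

#' Forward birth-death-fossilization simulation
#'
#' Simulates taxa forward in time over a stage grid with piecewise-constant
#' speciation (lambda), extinction (mu) and fossil sampling (psi) rates,
#' using exact event times (competing exponentials per lineage, rates
#' switching at stage boundaries; no time discretization).  Speciation is
#' budding: the mother taxon persists through the event and the daughter is
#' a new taxon.  Fossil occurrences are Poisson(psi_stage) events along
#' each taxon's duration.
#'
#' @param stages Data frame (name, start_ma, end_ma, lambda, mu, psi),
#'   contiguous, oldest first; ages in Ma, `start_ma > end_ma`.
#' @param n_founders Number of independent founder lineages started at the
#'   oldest boundary.
#' @param seed Integer seed.
#' @param taxon_cap Abort threshold against explosive growth.
#' @return List: `taxa` (data frame id, parent, origin_ma, extinction_ma
#'   with `NA` for taxa extant at the young end, extinct, n_occ),
#'   `occurrences` (list of occurrence-age vectors per taxon) and the
#'   simulation settings.  The `parent` column is the taxon-level genealogy
#'   (the true tree under budding speciation).
#' @export
gen_fbd_record <- function(stages, n_founders = 1L, seed = 1L,
                           taxon_cap = 200000L) {
  need <- c("start_ma", "end_ma", "lambda", "mu", "psi")
  stopifnot(all(need %in% names(stages)), nrow(stages) >= 1L)
  stages <- stages[order(-stages$start_ma), , drop = FALSE]
  if (any(stages$start_ma <= stages$end_ma)) stop("need start_ma > end_ma")
  if (any(stages$lambda < 0 | stages$mu < 0 | stages$psi < 0))
    stop("rates must be non-negative")
  t_old <- stages$start_ma[1L]
  t_young <- stages$end_ma[nrow(stages)]
  set.seed(seed)
  id <- integer(0); parent <- integer(0)
  origin <- numeric(0); extinct_at <- numeric(0)
  # active queue: (taxon id, current age)
  queue_id <- seq_len(n_founders)
  queue_age <- rep(t_old, n_founders)
  id <- queue_id; parent <- rep(NA_integer_, n_founders)
  origin <- rep(t_old, n_founders); extinct_at <- rep(NA_real_, n_founders)
  next_id <- n_founders + 1L
  qi <- 1L
  while (qi <= length(queue_id)) {
    tx <- queue_id[qi]; t <- queue_age[qi]; qi <- qi + 1L
    repeat {
      s <- .stage_at(stages, t)
      if (is.na(s) || t <= t_young) break       # survived to the young end
      lam <- stages$lambda[s]; mu <- stages$mu[s]
      tot <- lam + mu
      bound <- max(stages$end_ma[s], t_young)
      if (tot == 0) { t <- bound; if (t <= t_young) break else next }
      wait <- stats::rexp(1L, tot)
      if (t - wait <= bound) { t <- bound; if (t <= t_young) break else next }
      t <- t - wait
      if (stats::runif(1L) < lam / tot) {       # budding speciation
        if (next_id > taxon_cap)
          stop("taxon cap (", taxon_cap, ") exceeded; lower lambda or ",
               "shorten the horizon")
        id <- c(id, next_id); parent <- c(parent, tx)
        origin <- c(origin, t); extinct_at <- c(extinct_at, NA_real_)
        queue_id <- c(queue_id, next_id); queue_age <- c(queue_age, t)
        next_id <- next_id + 1L
      } else {                                  # extinction
        extinct_at[tx] <- t
        break
      }
    }
  }
  # Poisson occurrences along each taxon's duration, per stage overlap
  n_taxa <- length(id)
  stop_age <- ifelse(is.na(extinct_at), t_young, extinct_at)
  occurrences <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    occ <- numeric(0)
    for (s in seq_len(nrow(stages))) {
      hi <- min(origin[i], stages$start_ma[s])
      lo <- max(stop_age[i], stages$end_ma[s])
      if (hi > lo && stages$psi[s] > 0) {
        k <- stats::rpois(1L, stages$psi[s] * (hi - lo))
        if (k > 0) occ <- c(occ, stats::runif(k, lo, hi))
      }
    }
    occurrences[[i]] <- sort(occ, decreasing = TRUE)
  }
  taxa <- data.frame(id = id, parent = parent, origin_ma = origin,
                     extinction_ma = extinct_at,
                     extinct = !is.na(extinct_at),
                     n_occ = vapply(occurrences, length, integer(1)))
  list(taxa = taxa, occurrences = occurrences, stages = stages,
       n_founders = n_founders, seed = seed)
}

.attach_sa_newick <- function(s, a, b) {
  # rewrite "...b:x..." as "...(b:x/2,a:0):x/2..." so that a becomes a
  # zero-length (sampled-ancestor) tip on b's lineage
  pat <- paste0("([(,])", b, ":([0-9.eE+-]+)")
  m <- regexec(pat, s)
  if (m[[1]][1] == -1) stop("tip '", b, "' not found in newick string")
  x <- as.numeric(regmatches(s, m)[[1]][3])
  h <- format(x / 2, digits = 17)
  sub(pat, paste0("\\1(", b, ":", h, ",", a, ":0):", h), s)
}

#' Generate a posterior-like tree sample with known AD support
#'
#' Writes `n_trees` random ultrametric-ish topologies over `taxa`; exactly
#' `round(ad_fraction * n_trees)` of them place taxon `pair[1]` as a
#' zero-length sampled-ancestor tip on the pendant lineage of `pair[2]`,
#' the remainder place it as an ordinary tip.  By construction
#' [ad_posterior()] on the written file returns `ad_fraction` exactly.
#'
#' @param n_trees Number of trees (>= 1).
#' @param taxa Character vector of tip labels (>= 2).
#' @param ad_fraction Fraction of trees containing the AD pair, in [0, 1].
#' @param seed Integer seed.
#' @param pair Length-2 character vector `(ancestor, descendant)`; default
#'   the first two taxa.
#' @param path Optional output path (Newick, one tree per line, `# seed`
#'   header); sidecar truth written alongside.
#' @return The `tree_sample` (invisibly when writing).
#' @export
gen_tree_sample <- function(n_trees, taxa, ad_fraction, seed = 1L,
                            pair = taxa[1:2], path = NULL) {
  stopifnot(n_trees >= 1L, length(taxa) >= 2L,
            ad_fraction >= 0, ad_fraction <= 1,
            all(pair %in% taxa), pair[1] != pair[2])
  n_ad <- round(ad_fraction * n_trees)
  set.seed(seed)
  strings <- character(n_trees)
  for (i in seq_len(n_trees)) {
    if (i <= n_ad) {
      rest <- setdiff(taxa, pair[1])
      tr <- ape::rtree(length(rest), tip.label = sample(rest))
      strings[i] <- .attach_sa_newick(ape::write.tree(tr), pair[1], pair[2])
    } else {
      tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
      strings[i] <- ape::write.tree(tr)
    }
  }
  truth <- list(seed = seed, n_trees = n_trees, ad_fraction = ad_fraction,
                n_ad = n_ad, ancestor = pair[1], descendant = pair[2])
  if (!is.null(path)) {
    writeLines(c(paste0("# seed: ", seed), strings), path)
    .write_truth(path, truth)
    out <- read_tree_sample(path)
    attr(out, "truth") <- truth
    return(invisible(out))
  }
  tmp <- tempfile(fileext = ".nwk")
  on.exit(unlink(tmp))
  writeLines(strings, tmp)
  out <- read_tree_sample(tmp)
  attr(out, "truth") <- truth
  out
}

#' Generate a taxon-by-interval occurrence table
#'
#' Each taxon's true range is a random contiguous block of intervals (both
#' endpoints uniform); within the range, presence in each interval is an
#' independent Bernoulli draw with that interval's sampling probability.
#'
#' @param n_taxa Number of taxa.
#' @param intervals Stage table data frame (name, start_ma, end_ma), oldest
#'   first.
#' @param p_sample Per-interval sampling probability, scalar or one value
#'   per interval, in [0, 1].
#' @param seed Integer seed.
#' @param path Optional CSV output path (columns taxon, interval, `# seed`
#'   header); sidecar truth written alongside.
#' @return The `occurrence_table` (invisibly when writing), with attribute
#'   `"truth"` (seed, p_sample, per-taxon true ranges).
#' @export
gen_occurrences <- function(n_taxa, intervals, p_sample, seed = 1L,
                            path = NULL) {
  stopifnot(n_taxa >= 1L, nrow(intervals) >= 1L)
  ni <- nrow(intervals)
  p <- rep(p_sample, length.out = ni)
  stopifnot(all(p >= 0 & p <= 1))
  set.seed(seed)
  e1 <- sample.int(ni, n_taxa, replace = TRUE)
  e2 <- sample.int(ni, n_taxa, replace = TRUE)
  from <- pmin(e1, e2); to <- pmax(e1, e2)
  rows <- vector("list", n_taxa)
  taxon_ids <- sprintf("t%04d", seq_len(n_taxa))
  for (i in seq_len(n_taxa)) {
    rng <- from[i]:to[i]
    hit <- rng[stats::runif(length(rng)) < p[rng]]
    if (length(hit))
      rows[[i]] <- data.frame(taxon = taxon_ids[i],
                              interval = intervals$name[hit])
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(taxon = character(0),
                                    interval = character(0))
  truth <- list(seed = seed, n_taxa = n_taxa, p_sample = p,
                range_from = intervals$name[from],
                range_to = intervals$name[to])
  occ <- occurrence_table(df, intervals)
  attr(occ, "truth") <- truth
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(paste0("# seed: ", seed), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    .write_truth(path, truth)
    return(invisible(occ))
  }
  occ
}
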