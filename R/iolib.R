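# Readers and writers for every external format the pipeline touches:
# measurement CSVs, event tables, stage tables, NEXUS character matrices,
# Newick/NEXUS tree samples (with sampled-ancestor and rate annotations),
# occurrence CSVs, FBD posterior CSVs and JSON run configurations.
#
# All CSVs may carry '#' comment lines (the generators write the seed there).

.read_csv <- function(path, required = character(0), what = "file") {
  if (!file.exists(path)) stop(what, " not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("format error in ", path, ": missing required column '",
         miss[1L], "'")
  df
}

.check_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (is.null(v)) next
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad))
      stop("format error in ", path, ": non-numeric value '", v[bad[1L]],
           "' in column '", col, "' at data row ", bad[1L])
    df[[col]] <- num
  }
  df
}

#' Read per-specimen plate measurements
#'
#' The CSV must have columns `locality`, `age_ma` and either `area` or the
#' pair `length`/`width`; optional columns `stage` and `event_phase` are
#' carried along.  Rows with an `area` value use it verbatim; otherwise the
#' area is computed with [plate_area()].
#'
#' @param path CSV path.
#' @param area_formula Passed to [plate_area()] for rows without `area`.
#' @return An [assemblage_series()], one assemblage per distinct locality,
#'   ordered oldest to youngest.
#' @export
read_measurements <- function(path, area_formula = c("rectangle", "ellipse")) {
  area_formula <- match.arg(area_formula)
  df <- .read_csv(path, required = c("locality", "age_ma"),
                  what = "measurement file")
  has_area <- "area" %in% names(df)
  has_lw <- all(c("length", "width") %in% names(df))
  if (!has_area && !has_lw)
    stop("format error in ", path,
         ": missing required column 'area' (or 'length' and 'width')")
  df <- .check_numeric(df, intersect(c("age_ma", "area", "length", "width"),
                                     names(df)), path)
  area <- if (has_area) df$area else rep(NA_real_, nrow(df))
  need <- is.na(area)
  if (any(need)) {
    if (!has_lw)
      stop("format error in ", path, ": row ", which(need)[1L],
           " has no area and no length/width")
    area[need] <- plate_area(df$length[need], df$width[need], area_formula)
  }
  assemblage_series(lapply(split(seq_len(nrow(df)), df$locality), function(i) {
    assemblage(locality = as.character(df$locality[i[1L]]),
               age_ma = df$age_ma[i[1L]],
               areas = area[i],
               stage = if ("stage" %in% names(df))
                 as.character(df$stage[i[1L]]) else NA_character_)
  }))
}

#' Write a series back to a measurement CSV
#'
#' Writes one row per measurement (columns locality, age_ma, stage, area);
#' `read_measurements(write_measurements(x))` reproduces all values to full
#' precision.  Series without raw measurements (summary-only) cannot be
#' written.
#'
#' @param series An `assemblage_series` holding raw areas.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series, path) {
  stopifnot(inherits(series, "assemblage_series"))
  rows <- lapply(series, function(a) {
    if (is.null(a$areas))
      stop("assemblage '", a$locality, "' has no raw measurements to write")
    data.frame(locality = a$locality, age_ma = a$age_ma, stage = a$stage,
               area = a$areas, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event-window table
#'
#' @param path CSV with columns `name`, `oldest`, `youngest`.
#' @return List of [event_window()] objects.
#' @export
read_events <- function(path) {
  df <- .read_csv(path, required = c("name", "oldest", "youngest"),
                  what = "event file")
  lapply(seq_len(nrow(df)), function(i)
    event_window(as.character(df$name[i]), as.character(df$oldest[i]),
                 as.character(df$youngest[i])))
}

#' Read a geological stage table
#'
#' No timescale is baked into the package; intervals are user input.
#' Intervals are half-open `[start_ma, end_ma)` with `start_ma > end_ma`
#' (ages in Ma before present).
#'
#' @param path CSV with columns `name`, `start_ma`, `end_ma`.
#' @return Data frame ordered oldest to youngest.
#' @export
read_stage_table <- function(path) {
  df <- .read_csv(path, required = c("name", "start_ma", "end_ma"),
                  what = "stage table")
  df <- .check_numeric(df, c("start_ma", "end_ma"), path)
  if (any(df$start_ma <= df$end_ma))
    stop("format error in ", path, ": start_ma must exceed end_ma (ages in ",
         "Ma before present) for interval '",
         df$name[df$start_ma <= df$end_ma][1L], "'")
  df$name <- as.character(df$name)
  df[order(-df$start_ma), , drop = FALSE]
}

# ---- NEXUS character matrix --------------------------------------------

#' Read a morphological character matrix from NEXUS
#'
#' Parses a CHARACTERS/DATA block (via \pkg{ape}) into a
#' `character_matrix`: ordered taxon labels plus per-taxon state strings
#' over the alphabet `0-9`, `?` (unknown) and `-` (inapplicable), the two
#' special tokens kept distinct.
#'
#' @param path NEXUS file path.
#' @return Object of class `"character_matrix"` with fields `taxa`,
#'   `states`, `n_taxa`, `n_chars`.
#' @export
read_nexus_matrix <- function(path) {
  if (!file.exists(path)) stop("NEXUS file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  dim_line <- grep("NCHAR\\s*=", txt, ignore.case = TRUE, value = TRUE)
  nchar_decl <- if (length(dim_line))
    as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dim_line[1L],
                   ignore.case = TRUE)) else NA_integer_
  m <- tryCatch(ape::read.nexus.data(path),
                error = function(e) stop("format error in ", path, ": ",
                                         conditionMessage(e)))
  taxa <- names(m)
  states <- vapply(m, paste, character(1), collapse = "")
  lens <- nchar(states)
  if (!is.na(nchar_decl) && any(lens != nchar_decl))
    stop("format error in ", path, ": state string of taxon '",
         taxa[lens != nchar_decl][1L], "' has length ",
         lens[lens != nchar_decl][1L], " but NCHAR=", nchar_decl,
         " (duplicate taxon labels are concatenated by the reader)")
  if (length(unique(lens)) != 1L)
    stop("format error in ", path, ": unequal state-string lengths")
  if (anyDuplicated(taxa))
    stop("format error in ", path, ": duplicate taxon label '",
         taxa[duplicated(taxa)][1L], "'")
  structure(list(taxa = taxa, states = unname(states),
                 n_taxa = length(taxa), n_chars = unname(lens[1L])),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character matrix:", x$n_taxa, "taxa x", x$n_chars, "characters\n")
  invisible(x)
}

#' Count unknown and inapplicable cells in a character matrix
#'
#' @param x A `character_matrix`.
#' @return Named list `unknown` (`?` count) and `inapplicable` (`-` count).
#' @export
matrix_missingness <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  all_states <- strsplit(paste(x$states, collapse = ""), "")[[1]]
  list(unknown = sum(all_states == "?"),
       inapplicable = sum(all_states == "-"))
}

# ---- tree samples ------------------------------------------------------

# Comment annotations ("[&rate=2.5]", "[&SA]") are not retained by ape's
# parser, so they are folded into node labels before parsing ("@@rate#2.5@@")
# and unfolded afterwards.  Comments written after a branch length are moved
# in front of the colon first.
.fold_comments <- function(s) {
  s <- gsub("\\[(?!&)[^]]*\\]", "", s, perl = TRUE)       # non-annotation comments
  s <- gsub(":([0-9.eE+-]+)\\[&([^]]*)\\]", "[&\\2]:\\1", s)
  # commas inside annotations would break newick labels: use '~' internally
  while (grepl("\\[&[^]]*,", s)) s <- sub("(\\[&[^]]*),", "\\1~", s)
  s <- gsub("\\[&([^]]*)\\]", "@@\\1@@", s)
  gsub("=", "#", s, fixed = TRUE)
}

.split_marker <- function(lab) {
  # returns list(label, annotation or NA)
  has <- grepl("@@", lab, fixed = TRUE)
  ann <- rep(NA_character_, length(lab))
  ann[has] <- sub("^.*?@@(.*)@@.*$", "\\1", lab[has])
  lab[has] <- sub("@@.*@@", "", lab[has])
  list(label = lab, annotation = ann)
}

.annotate_tree <- function(tr, sa_branch_tolerance) {
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  tipann <- .split_marker(tr$tip.label)
  tr$tip.label <- tipann$label
  nodeann <- .split_marker(if (is.null(tr$node.label))
    rep("", nnode) else tr$node.label)
  tr$node.label <- NULL
  ann <- c(tipann$annotation, nodeann$annotation)   # indexed by node id
  # per-edge rate multipliers from "rate#<x>" on the child node
  rate <- rep(NA_real_, nrow(tr$edge))
  child <- tr$edge[, 2L]
  rspec <- regmatches(ann, regexpr("rate#[0-9.eE+-]+", ann))
  has_rate <- grepl("rate#", ann) & !is.na(ann)
  if (any(has_rate)) {
    vals <- as.numeric(sub("rate#", "", unlist(rspec)))
    rate_by_node <- rep(NA_real_, ntip + nnode)
    rate_by_node[which(has_rate)] <- vals
    rate <- rate_by_node[child]
  }
  # sampled-ancestor flags: explicit SA token overrides the length rule
  explicit_sa <- !is.na(ann[seq_len(ntip)]) &
    grepl("(^|~)SA(~|$)", ann[seq_len(ntip)])
  pend <- tr$edge.length[match(seq_len(ntip), child)]
  if (any(pend < 0)) stop("negative branch length in tree")
  sa <- explicit_sa | pend <= sa_branch_tolerance
  tr$sampled_ancestor <- stats::setNames(sa, tr$tip.label)
  tr$edge_rate <- rate
  tr
}

#' Read a posterior tree sample
#'
#' Accepts a Newick file (one tree per line) or a NEXUS trees file.  Two
#' sampled-ancestor conventions are recognised and both are first-class: a
#' tip whose pendant branch length is `<= sa_branch_tolerance`, or a tip
#' annotated with an `[&SA]` comment (the annotation overrides the length
#' rule).  Per-branch rate multipliers in `[&rate=<x>]` comments are
#' retained on the edge subtending the annotated node.
#'
#' @param path Tree file path.
#' @param sa_branch_tolerance Pendant-branch duration (Myr) at or below
#'   which a tip is flagged as a sampled ancestor (default `1e-8`).
#' @return Object of class `"tree_sample"`: a list of `phylo` trees, each
#'   with components `sampled_ancestor` (named logical over tips) and
#'   `edge_rate` (numeric per edge, `NA` where unannotated).
#' @export
read_tree_sample <- function(path, sa_branch_tolerance = 1e-8) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  stopifnot(sa_branch_tolerance >= 0)
  txt <- readLines(path, warn = FALSE)
  is_nexus <- any(grepl("^#NEXUS", txt, ignore.case = TRUE))
  strings <- if (is_nexus) {
    tl <- grep("^\\s*tree\\s+\\S+\\s*=", txt, ignore.case = TRUE, value = TRUE)
    sub("^\\s*tree\\s+\\S+\\s*=\\s*(\\[[^]]*\\]\\s*)?", "", tl,
        ignore.case = TRUE)
  } else {
    keep <- txt[nzchar(trimws(txt))]
    keep[!startsWith(trimws(keep), "#")]   # tolerate '# seed: ...' headers
  }
  if (length(strings) == 0L) stop("no trees found in ", path)
  trees <- vector("list", length(strings))
  for (i in seq_along(strings)) {
    tr <- tryCatch(ape::read.tree(text = .fold_comments(strings[i])),
                   error = function(e) NULL)
    if (is.null(tr))
      stop("format error: unparseable tree string at index ", i, " in ", path)
    trees[[i]] <- .annotate_tree(tr, sa_branch_tolerance)
  }
  tree_sample(trees)
}

#' Assemble a tree sample from `phylo` objects
#'
#' @param trees List of `phylo` trees (annotations optional; missing
#'   `sampled_ancestor`/`edge_rate` components are filled with
#'   all-`FALSE`/all-`NA`).
#' @return Object of class `"tree_sample"`.
#' @export
tree_sample <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  taxa <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) stop("element ", i, " is not a phylo tree")
    if (is.null(tr$sampled_ancestor))
      tr$sampled_ancestor <- stats::setNames(
        rep(FALSE, length(tr$tip.label)), tr$tip.label)
    if (is.null(tr$edge_rate)) tr$edge_rate <- rep(NA_real_, nrow(tr$edge))
    if (!identical(sort(tr$tip.label), taxa))
      warning("tree ", i, " has a different taxon set than tree 1")
    trees[[i]] <- tr
  }
  structure(list(trees = trees, n_trees = length(trees)),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree sample:", x$n_trees, "trees,",
      length(x$trees[[1L]]$tip.label), "tips\n")
  invisible(x)
}

.unfold_tree <- function(tr) {
  # embed annotations back into labels, serialize, restore [&...] syntax
  ntip <- length(tr$tip.label)
  ann <- rep("", ntip + tr$Nnode)
  sa <- tr$sampled_ancestor[tr$tip.label]
  rate <- tr$edge_rate
  child <- tr$edge[, 2L]
  for (k in seq_along(child)) {
    if (!is.na(rate[k]))
      ann[child[k]] <- paste0("rate#", format(rate[k], digits = 17))
  }
  if (any(sa)) {
    idx <- which(sa)
    ann[idx] <- ifelse(nzchar(ann[idx]), paste0("SA~", ann[idx]), "SA")
  }
  mark <- ifelse(nzchar(ann), paste0("@@", ann, "@@"), "")
  tr$tip.label <- paste0(tr$tip.label, mark[seq_len(ntip)])
  tr$node.label <- mark[(ntip + 1L):(ntip + tr$Nnode)]
  s <- ape::write.tree(tr)
  s <- gsub("@@([^@]*)@@", "[&\\1]", s)
  s <- gsub("#", "=", s, fixed = TRUE)
  # restore commas inside annotations ('~' is the internal separator)
  while (grepl("\\[&[^]]*~", s)) s <- sub("(\\[&[^]]*)~", "\\1,", s)
  s
}

#' Write a tree sample as annotated Newick
#'
#' One tree per line; sampled-ancestor tips carry `[&SA]` and annotated
#' branches `[&rate=<x>]`, in the dialect [read_tree_sample()] reads back.
#'
#' @param sample A `tree_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(sample, path) {
  stopifnot(inherits(sample, "tree_sample"))
  writeLines(vapply(sample$trees, .unfold_tree, character(1)), path)
  invisible(path)
}

# ---- occurrences and FBD posteriors ------------------------------------

#' Read a taxon-by-interval occurrence table
#'
#' @param path CSV with columns `taxon`, `interval`.
#' @param stage_table Data frame from [read_stage_table()] giving the
#'   interval ordering.
#' @return Object of class `"occurrence_table"`: 0/1 matrix `presence`
#'   (taxa in rows, intervals in columns oldest to youngest) plus the
#'   `intervals` table.
#' @export
read_occurrences <- function(path, stage_table) {
  df <- .read_csv(path, required = c("taxon", "interval"),
                  what = "occurrence file")
  occurrence_table(df, stage_table)
}

#' Build an occurrence table from a data frame
#'
#' @param df Data frame with columns `taxon`, `interval`; duplicates are
#'   collapsed.
#' @param stage_table Interval table (see [read_stage_table()]).
#' @return An `"occurrence_table"`.
#' @export
occurrence_table <- function(df, stage_table) {
  stopifnot(all(c("name", "start_ma", "end_ma") %in% names(stage_table)))
  intervals <- stage_table[order(-stage_table$start_ma), , drop = FALSE]
  unknown <- setdiff(unique(as.character(df$interval)), intervals$name)
  if (length(unknown))
    stop("interval '", unknown[1L], "' not present in the stage table")
  taxa <- sort(unique(as.character(df$taxon)))
  pres <- matrix(0L, nrow = length(taxa), ncol = nrow(intervals),
                 dimnames = list(taxa, intervals$name))
  if (nrow(df) > 0L)
    pres[cbind(match(as.character(df$taxon), taxa),
               match(as.character(df$interval), intervals$name))] <- 1L
  structure(list(presence = pres, intervals = intervals),
            class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("occurrence table:", nrow(x$presence), "taxa x",
      ncol(x$presence), "intervals,", sum(x$presence), "presences\n")
  invisible(x)
}

#' Read per-stage FBD posterior draws
#'
#' @param path CSV with columns `stage`, `lambda`, `mu`, `psi` (one row per
#'   posterior draw per stage).
#' @return Data frame of draws; all rates must be non-negative.
#' @export
read_fbd_posterior <- function(path) {
  df <- .read_csv(path, required = c("stage", "lambda", "mu", "psi"),
                  what = "FBD posterior file")
  df <- .check_numeric(df, c("lambda", "mu", "psi"), path)
  if (any(df$lambda < 0 | df$mu < 0 | df$psi < 0, na.rm = TRUE))
    stop("format error in ", path, ": negative rate")
  df$stage <- as.character(df$stage)
  df
}

# ---- run configuration -------------------------------------------------

#' Build a run configuration
#'
#' @param seed Master RNG seed (integer).
#' @param n_sims Number of Monte Carlo simulations (default 10000).
#' @param area_formula `"rectangle"` or `"ellipse"`.
#' @param tail p-value tail: `"decrease"` (default), `"increase"` or
#'   `"two_sided"`.
#' @param min_n Minimum per-locality sample size (default 2).
#' @param sa_branch_tolerance Sampled-ancestor pendant-length tolerance in
#'   Myr (default `1e-8`).
#' @param permutation `"pool"` (reassign pooled values) or `"age-shuffle"`
#'   (shuffle locality ages).
#' @param ... Further entries (file paths etc.) stored verbatim.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_sims = 10000L,
                       area_formula = c("rectangle", "ellipse"),
                       tail = c("decrease", "increase", "two_sided"),
                       min_n = 2L, sa_branch_tolerance = 1e-8,
                       permutation = c("pool", "age-shuffle"), ...) {
  area_formula <- match.arg(area_formula)
  tail <- match.arg(tail)
  permutation <- match.arg(permutation)
  stopifnot(n_sims >= 1L, min_n >= 1L, sa_branch_tolerance >= 0)
  structure(c(list(seed = as.integer(seed), n_sims = as.integer(n_sims),
                   area_formula = area_formula, tail = tail,
                   min_n = as.integer(min_n),
                   sa_branch_tolerance = sa_branch_tolerance,
                   permutation = permutation),
              list(...)),
            class = "run_config")
}

#' Read a JSON run configuration
#'
#' @param path JSON file whose entries are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
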