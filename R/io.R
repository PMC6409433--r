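# Plain-text SFS table format and run configuration.
#
# SFS table: comment/header lines start with '#'.  Two headers are
# mandatory, '#n=<int>' and '#folded=<0|1>'.  Each data row is
#   locus_id <TAB> m <TAB> x <TAB> c_1 <TAB> ... <TAB> c_L
# where x is the substitution count or '.', and L = n-1 (unfolded) or
# floor(n/2) (folded).  Derived-allele classes run 1..n-1 and minor-allele
# classes 1..floor(n/2); the invariant classes 0 and n are never stored.

#' Read an SFS table
#'
#' @param path File path.
#' @return An [sfs_dataset()].
#' @export
read_sfs_table <- function(path) {
  lines <- readLines(path)
  n <- NA_integer_; folded <- NA
  for (ln in lines[startsWith(lines, "#")]) {
    if (grepl("^#n=", ln)) n <- as.integer(sub("^#n=", "", ln))
    if (grepl("^#folded=", ln)) folded <- sub("^#folded=", "", ln) == "1"
  }
  if (is.na(n)) stop("missing '#n=' header in ", path)
  if (is.na(folded)) stop("missing '#folded=' header in ", path)
  L <- if (folded) n %/% 2L else n - 1L
  rows <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(rows)) stop("no data rows in ", path)
  ids <- character(0); m <- numeric(0); x <- numeric(0)
  counts <- matrix(0, 0L, L)
  has_x <- FALSE
  for (r in rows) {
    fields <- strsplit(lines[r], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 3L + L)
      stop(sprintf("line %d: expected %d fields, found %d",
                   r, 3L + L, length(fields)))
    cc <- suppressWarnings(as.numeric(fields[-(1:3)]))
    if (any(is.na(cc)) || any(cc < 0) || any(cc != round(cc)))
      stop(sprintf("line %d: counts must be non-negative integers", r))
    mm <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(mm) || mm <= 0 || mm != round(mm))
      stop(sprintf("line %d: m must be a positive integer", r))
    xx <- if (fields[3L] == ".") NA_real_ else
      suppressWarnings(as.numeric(fields[3L]))
    if (!is.na(xx) && (xx < 0 || xx != round(xx)))
      stop(sprintf("line %d: x must be '.' or a non-negative integer", r))
    if (fields[1L] %in% ids)
      stop(sprintf("line %d: duplicate locus id '%s'", r, fields[1L]))
    ids <- c(ids, fields[1L]); m <- c(m, mm); x <- c(x, xx)
    counts <- rbind(counts, cc)
    if (!is.na(xx)) has_x <- TRUE
  }
  if (has_x && any(is.na(x)))
    stop("substitution counts must be given for all loci or none")
  sfs_dataset(counts, m, n, x = if (has_x) x else NULL, folded = folded,
              ids = ids)
}

#' Write an SFS table
#'
#' Inverse of [read_sfs_table()]: `write(read(f))` reproduces `f` up to
#' comments.
#'
#' @param data An [sfs_dataset()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sfs_table <- function(data, path) {
  K <- nrow(data$counts)
  xcol <- if (is.null(data$x)) rep(".", K) else
    format(data$x, scientific = FALSE, trim = TRUE)
  rows <- vapply(seq_len(K), function(k)
    paste(c(data$ids[k],
            format(data$m[k], scientific = FALSE, trim = TRUE), xcol[k],
            format(data$counts[k, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t"), character(1))
  writeLines(c(sprintf("#n=%d", data$n),
               sprintf("#folded=%d", as.integer(data$folded)), rows), path)
  invisible(path)
}

## ---- run configuration -----------------------------------------------------

.known_config_keys <- c("model", "inference", "bootstrap", "output")

#' Read a run configuration (YAML)
#'
#' A configuration has up to four blocks: `model` (fields `H`, `tau`,
#' `shared_g`, `ref`, `divergence: {c, t}`, and `loci`, a list of records
#' with `theta`, `f`, `g`, `m`, `epsilon`), `inference` (`n_starts`, `seed`,
#' `use_profile`, `use_divergence`, `fit_epsilon`), `bootstrap` (`B`,
#' `level`) and `output`.  Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Build a model from a configuration's model block
#'
#' @param block The `model` element of [read_run_config()] output.
#' @return A [model_spec()].
#' @export
model_from_config <- function(block) {
  if (is.null(block$loci)) stop("model block has no loci")
  tau <- as.numeric(block$tau %||% numeric(0))
  loci <- lapply(block$loci, function(lc)
    locus_model(theta = lc$theta %||% 1e-3, f = lc$f %||% 1,
                g = as.numeric(lc$g %||% rep(1, length(tau))),
                m = lc$m, epsilon = lc$epsilon %||% 0))
  model_spec(epoch_model(tau), loci,
             shared_g = isTRUE(block$shared_g),
             divergence = block$divergence,
             ref = block$ref %||% 1L)
}
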