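#' Position weight matrix
#'
#' Constructs a PWM object from a 4 x L count (or frequency) matrix with rows
#' A, C, G, T. Counts are converted to per-column frequencies, a pseudocount
#' is added to every cell and columns are renormalized; the log-odds matrix
#' against the background composition and the per-column score bounds used
#' for min-max normalization are precomputed.
#'
#' @param counts Numeric 4 x L matrix, rows in A, C, G, T order (rownames
#'   optional but, when present, must be a permutation of A/C/G/T).
#' @param id,name Identifier and display name.
#' @param background Background base composition (length 4, sums to 1).
#' @param pseudocount Added to every frequency cell before renormalization.
#' @return An object of class `pwm` with elements `id`, `name`, `counts`,
#'   `freq`, `background`, `lom` (natural-log odds), `score_min`,
#'   `score_max`, `consensus`.
#' @export
pwm <- function(counts, id = "PWM1", name = id,
                background = rep(0.25, 4), pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("PWM must have at least one column")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("PWM entries must be finite and non-negative")
  }
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), c("A", "C", "G", "T"))) {
      stop("PWM row names must be A, C, G, T")
    }
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  }
  rownames(counts) <- c("A", "C", "G", "T")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("PWM column with zero total at column(s): ",
                         paste(which(cs == 0), collapse = ", "))
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 positive frequencies")
  }
  background <- background / sum(background)
  freq <- sweep(counts, 2, cs, "/") + pseudocount
  freq <- sweep(freq, 2, colSums(freq), "/")
  lom <- log(freq / background)
  structure(list(
    id = id, name = name, counts = counts, freq = freq,
    background = background, pseudocount = pseudocount, lom = lom,
    score_min = sum(apply(lom, 2, min)),
    score_max = sum(apply(lom, 2, max)),
    consensus = paste0(c("A", "C", "G", "T")[apply(freq, 2, which.max)],
                       collapse = "")
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s): length %d, consensus %s\n",
              x$id, x$name, ncol(x$freq), x$consensus))
  invisible(x)
}

pwm_length <- function(p) ncol(p$freq)

#' Read motifs in JASPAR PFM text format
#'
#' Parses the JASPAR 2016+ plain-text format: a `>ID NAME` header followed by
#' four rows, one per base, either labelled (`A [ 3 5 ... ]`) or bare
#' whitespace-separated numbers in A, C, G, T order.
#'
#' @param path Path to the PFM file.
#' @param background,pseudocount Passed to [pwm()].
#' @return A named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' motif headers found in ", path)
  out <- list()
  for (i in seq_along(headers)) {
    h <- headers[i]
    last <- if (i < length(headers)) headers[i + 1] - 1L else length(lines)
    body <- (h + 1L):last
    body <- body[keep[body]]
    if (length(body) != 4L) {
      stop("motif at line ", h, ": expected 4 base rows, found ",
           length(body))
    }
    hdr <- sub("^>\\s*", "", lines[h])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    labels <- character(4)
    rows <- vector("list", 4)
    for (k in seq_len(4)) {
      ln <- lines[body[k]]
      m <- regmatches(ln, regexec("^\\s*([A-Za-z])\\s*\\[(.*)\\]\\s*$", ln))[[1]]
      if (length(m) == 3L) {
        labels[k] <- toupper(m[2])
        numtxt <- m[3]
      } else {
        labels[k] <- c("A", "C", "G", "T")[k]
        numtxt <- ln
      }
      vals <- suppressWarnings(as.numeric(strsplit(trimws(numtxt), "\\s+")[[1]]))
      if (length(vals) == 0L || anyNA(vals)) {
        stop("unparseable matrix row at line ", body[k])
      }
      rows[[k]] <- vals
    }
    if (!setequal(labels, c("A", "C", "G", "T"))) {
      stop("motif at line ", h, ": row labels must be A, C, G, T (got ",
           paste(labels, collapse = ","), ")")
    }
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("motif at line ", h, ": rows of unequal length (",
           paste(lens, collapse = ","), ")")
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- labels
    out[[id]] <- pwm(mat[c("A", "C", "G", "T"), , drop = FALSE], id = id,
                     name = name, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' Write motifs in JASPAR PFM text format
#'
#' Writes the stored count matrices, so that a write/read round trip
#' reproduces the parsed frequencies exactly.
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE,
                                      scientific = FALSE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

# DNA helpers -----------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

dna_codes <- function(seqs) {
  # character vector of equal-length sequences -> integer matrix (NA = non-ACGT)
  n <- length(seqs)
  plen <- unique(nchar(seqs))
  stopifnot(length(plen) == 1L)
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  m <- match(chars, DNA_BASES)
  dim(m) <- dim(chars)
  m
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Reverse-complement a pwm's log-odds matrix: scanning the forward sequence
# with the rc matrix equals scanning the reverse complement with the original.
lom_revcomp <- function(lom) lom[4:1, rev(seq_len(ncol(lom))), drop = FALSE]

scan_codes <- function(codes, lom) {
  # codes: n x plen integer matrix; returns n x n_off raw score matrix
  L <- ncol(lom)
  plen <- ncol(codes)
  n_off <- plen - L + 1L
  if (n_off < 1L) stop("sequence shorter than motif")
  n <- nrow(codes)
  S <- matrix(0, n, n_off)
  for (j in seq_len(L)) {
    lomj <- lom[, j]
    block <- codes[, j:(j + n_off - 1L), drop = FALSE]
    # indexing preserves column-major order, so the vector aligns with S
    S <- S + lomj[block]
  }
  S
}

# Fast row maximum with NA-offset semantics (all-NA row -> NA).
scan_row_max <- function(S) {
  S[is.na(S)] <- -Inf
  v <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  v[v == -Inf] <- NA_real_
  v
}

#' Best normalized PWM match score of a sequence
#'
#' Scans both strands at every offset, takes the maximum log-odds sum and
#' min-max normalizes it to `[0, 1]` using the PWM's best and worst possible
#' site scores. Offsets containing non-ACGT characters are skipped; if every
#' offset is skipped the score is `NA`.
#'
#' @param seq A DNA string (character scalar).
#' @param pwm A [pwm()] object.
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return Normalized score in `[0, 1]`, or `NA`.
#' @export
best_site_score <- function(seq, pwm, both_strands = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  scan_best_scores(seq, pwm, both_strands = both_strands)
}

#' Best normalized match scores for a set of promoters
#'
#' Vectorized form of [best_site_score()] over many equal-length sequences.
#'
#' @param promoters Character vector of DNA sequences (named by gene).
#' @param pwm A [pwm()] object.
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return Named numeric vector of normalized best scores.
#' @export
scan_best_scores <- function(promoters, pwm, both_strands = TRUE) {
  lens <- nchar(promoters)
  if (any(lens < pwm_length(pwm))) {
    stop("sequence(s) shorter than the motif (", pwm_length(pwm), " bp)")
  }
  if (length(unique(lens)) > 1L) {
    return(vapply(promoters, scan_best_scores, numeric(1), pwm = pwm,
                  both_strands = both_strands))
  }
  codes <- dna_codes(promoters)
  out <- scan_best_scores_codes(codes, pwm, both_strands)
  names(out) <- names(promoters)
  out
}

scan_best_scores_codes <- function(codes, pwm, both_strands = TRUE) {
  best <- scan_row_max(scan_codes(codes, pwm$lom))
  if (both_strands) {
    best <- suppressWarnings(pmax(
      best, scan_row_max(scan_codes(codes, lom_revcomp(pwm$lom))),
      na.rm = TRUE))
  }
  # clamp: summation order can overshoot the closed-form bounds by ~1e-16
  pmin(pmax((best - pwm$score_min) / (pwm$score_max - pwm$score_min), 0), 1)
}

#' Promoter motif enrichment by population z-test
#'
#' For each PWM, compares the mean best promoter match score of a foreground
#' gene set against the full promoter population (Pscan-style): the
#' background is treated as the population, so
#' `z = (fg_mean - bg_mean) / (bg_sd / sqrt(n_fg))` with the population
#' (denominator N) standard deviation, one-sided upper p, and Bonferroni
#' correction across motifs.
#'
#' @param fg_gene_ids Character vector of foreground gene ids.
#' @param promoters Named character vector of promoter sequences (the
#'   population), or a `genome_bundle` from [simulate_genome()].
#' @param pwms List of [pwm()] objects.
#' @param welch If `TRUE`, use a Welch two-sample z-test of foreground vs
#'   non-foreground instead of the population test.
#' @return A data.frame (class `motif_enrichment`) with one row per motif:
#'   `pwm_id`, `name`, `fg_mean`, `bg_mean`, `bg_sd`, `z`, `p`,
#'   `p_bonferroni`, `n_fg`, `n_bg`.
#' @export
motif_enrichment <- function(fg_gene_ids, promoters, pwms, welch = FALSE) {
  if (inherits(promoters, "genome_bundle")) promoters <- promoters$promoters
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(promoters))) stop("promoters must be named by gene id")
  fg_gene_ids <- unique(fg_gene_ids)
  if (length(fg_gene_ids) == 0) stop("empty foreground gene set")
  missing <- setdiff(fg_gene_ids, names(promoters))
  if (length(missing)) {
    stop("foreground gene(s) absent from the promoter population: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  same_len <- length(unique(nchar(promoters))) == 1L
  codes <- if (same_len) dna_codes(promoters) else NULL
  rows <- lapply(pwms, function(p) {
    sc <- if (same_len) {
      stats::setNames(scan_best_scores_codes(codes, p), names(promoters))
    } else {
      scan_best_scores(promoters, p)
    }
    sc <- sc[!is.na(sc)]
    fg <- sc[intersect(fg_gene_ids, names(sc))]
    n_fg <- length(fg); n_bg <- length(sc)
    bg_mean <- mean(sc)
    bg_sd <- stats::sd(sc) * sqrt((n_bg - 1) / n_bg)
    if (!is.finite(bg_sd) || bg_sd == 0) {
      warning("motif ", p$id, ": zero background score variance, skipped")
      return(NULL)
    }
    if (welch) {
      bgo <- sc[setdiff(names(sc), fg_gene_ids)]
      z <- (mean(fg) - mean(bgo)) /
        sqrt(stats::var(fg) / n_fg + stats::var(bgo) / length(bgo))
    } else {
      z <- (mean(fg) - bg_mean) / (bg_sd / sqrt(n_fg))
    }
    data.frame(pwm_id = p$id, name = p$name, fg_mean = mean(fg),
               bg_mean = bg_mean, bg_sd = bg_sd, z = z,
               p = stats::pnorm(z, lower.tail = FALSE),
               n_fg = n_fg, n_bg = n_bg, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(pwm_id = character(), name = character(),
                      fg_mean = numeric(), bg_mean = numeric(),
                      bg_sd = numeric(), z = numeric(), p = numeric(),
                      n_fg = integer(), n_bg = integer())
  }
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  rownames(res) <- NULL
  class(res) <- c("motif_enrichment", "data.frame")
  res
}
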