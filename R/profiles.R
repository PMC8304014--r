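#' Sequencing error and base-quality profiles
#'
#' An error profile gives, for each cycle position along a read and each
#' template base, the probability of calling each of the three alternative
#' bases. A quality profile gives the Phred-quality mean and spread for each
#' (position, base), separately for correctly-called and substituted bases.
#' Both are dense arrays internally; the file format (see
#' [load_profiles()]) is a sparse tab-separated table with `*` wildcards.
#'
#' @name profiles
NULL

QUAL_MIN <- 2L
QUAL_MAX <- 41L

#' @keywords internal
new_error_profile <- function(p) {
  # p: positions x 4 (ref) x 4 (alt), diagonal zero
  check_that(all(p >= 0 & p <= 1), "error probabilities must lie in [0,1]")
  tot <- apply(p, c(1, 2), sum)
  check_that(all(tot <= 1 + 1e-12),
             "total substitution probability per (position, base) must be <= 1")
  structure(list(p = p, max_len = dim(p)[1]), class = "error_profile")
}

#' @keywords internal
new_quality_profile <- function(mean_q, sd_q, error_mean_q, error_sd_q) {
  check_that(all(sd_q >= 0) && all(error_sd_q >= 0),
             "quality spreads must be non-negative")
  structure(list(mean_q = mean_q, sd_q = sd_q,
                 error_mean_q = error_mean_q, error_sd_q = error_sd_q,
                 max_len = dim(mean_q)[1]),
            class = "quality_profile")
}

#' Uniform (flat) error profile
#'
#' Every base at every position substitutes with total probability `rate`,
#' split equally across the three alternative bases.
#'
#' @param rate total per-base substitution probability (default 1e-3).
#' @param max_len number of read positions covered (default 150).
#' @return an `error_profile`.
#' @export
uniform_error_profile <- function(rate = 1e-3, max_len = 150L) {
  check_that(rate >= 0 && rate <= 1, "rate must be in [0,1]")
  p <- array(rate / 3, dim = c(max_len, 4, 4),
             dimnames = list(NULL, DNA_BASES, DNA_BASES))
  for (b in 1:4) p[, b, b] <- 0
  new_error_profile(p)
}

#' Default quality profile
#'
#' Gaussian Phred qualities, clamped to \[2, 41\]: one (mean, sd) for
#' correctly sequenced bases and a lower one for substituted bases, constant
#' across positions and bases.
#'
#' @param mean_q,sd_q quality of correct calls (default 37, 2).
#' @param error_mean_q,error_sd_q quality of substituted calls (default
#'   25, 5).
#' @param max_len number of read positions covered (default 150).
#' @return a `quality_profile`.
#' @export
default_quality_profile <- function(mean_q = 37, sd_q = 2,
                                    error_mean_q = 25, error_sd_q = 5,
                                    max_len = 150L) {
  dn <- list(NULL, DNA_BASES)
  m <- matrix(mean_q, max_len, 4, dimnames = dn)
  s <- matrix(sd_q, max_len, 4, dimnames = dn)
  em <- matrix(error_mean_q, max_len, 4, dimnames = dn)
  es <- matrix(error_sd_q, max_len, 4, dimnames = dn)
  new_quality_profile(m, s, em, es)
}

parse_profile_table <- function(path, n_cols, col_names) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_cols)
  if (length(bad) > 0)
    stop(sprintf("malformed row in profile file '%s' at line %d: expected %d tab-separated fields",
                 path, bad[1], n_cols), call. = FALSE)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- col_names
  if (identical(tolower(df[1, 1]), col_names[1])) df <- df[-1, , drop = FALSE]
  df
}

expand_wildcard_pos <- function(x, max_len) {
  if (x == "*") seq_len(max_len) else {
    i <- suppressWarnings(as.integer(x)) + 1L   # file positions are 0-based
    if (is.na(i) || i < 1) stop("invalid position field: ", x, call. = FALSE)
    i
  }
}

expand_wildcard_base <- function(x) {
  if (x == "*") 1:4 else {
    i <- match(toupper(x), DNA_BASES)
    if (is.na(i)) stop("invalid base field: ", x, call. = FALSE)
    i
  }
}

#' Load error and quality profiles from tab-separated files
#'
#' Error file columns: `position ref_base alt_base probability`; quality
#' file columns: `position base mean_q sd_q is_error`. Positions are 0-based
#' read-cycle indices; `*` is a wildcard for position or base; later rows
#' override earlier ones. Cells never mentioned keep a documented uniform
#' default (error: `default_rate/3` per alternative; quality: the
#' [default_quality_profile()] values), and a warning reports that the
#' default was used. An empty (or comment-only) file therefore yields the
#' pure default profile with a warning.
#'
#' @param error_path,quality_path profile file paths.
#' @param max_len number of read positions to cover (default 150; reads
#'   longer than the profile reuse its last position).
#' @param default_rate fallback total substitution probability for error
#'   cells not covered by the file (default 1e-3).
#' @return list with elements `error` (`error_profile`) and `quality`
#'   (`quality_profile`).
#' @export
load_profiles <- function(error_path, quality_path, max_len = 150L,
                          default_rate = 1e-3) {
  list(error = load_error_profile(error_path, max_len, default_rate),
       quality = load_quality_profile(quality_path, max_len))
}

#' @rdname load_profiles
#' @export
load_error_profile <- function(error_path, max_len = 150L,
                               default_rate = 1e-3) {
  check_that(file.exists(error_path),
             sprintf("error profile file not found: %s", error_path))
  df <- parse_profile_table(error_path, 4,
                            c("position", "ref_base", "alt_base", "probability"))
  prof <- uniform_error_profile(default_rate, max_len)
  covered <- array(FALSE, dim = c(max_len, 4, 4))
  if (is.null(df) || nrow(df) == 0) {
    warning(sprintf("error profile '%s' has no data rows; uniform default rate %g used everywhere",
                    error_path, default_rate))
    return(prof)
  }
  p <- prof$p
  for (r in seq_len(nrow(df))) {
    prob <- suppressWarnings(as.numeric(df$probability[r]))
    if (is.na(prob) || prob < 0 || prob > 1)
      stop(sprintf("error profile '%s': probability '%s' outside [0,1]",
                   error_path, df$probability[r]), call. = FALSE)
    pos <- expand_wildcard_pos(df$position[r], max_len)
    pos <- pos[pos <= max_len]
    ref <- expand_wildcard_base(df$ref_base[r])
    alt <- expand_wildcard_base(df$alt_base[r])
    for (b in ref) for (a in alt) {
      if (a == b) next
      # a wildcard alt row spreads its total probability over the 3 alts
      val <- if (df$alt_base[r] == "*") prob / 3 else prob
      p[pos, b, a] <- val
      covered[pos, b, a] <- TRUE
    }
  }
  for (b in 1:4) covered[, b, b] <- TRUE
  if (!all(covered))
    warning(sprintf("error profile '%s' leaves %d (position, ref, alt) cells unspecified; uniform default rate %g used for them",
                    error_path, sum(!covered), default_rate))
  new_error_profile(p)
}

#' @rdname load_profiles
#' @export
load_quality_profile <- function(quality_path, max_len = 150L) {
  check_that(file.exists(quality_path),
             sprintf("quality profile file not found: %s", quality_path))
  df <- parse_profile_table(quality_path, 5,
                            c("position", "base", "mean_q", "sd_q", "is_error"))
  prof <- default_quality_profile(max_len = max_len)
  if (is.null(df) || nrow(df) == 0) {
    warning(sprintf("quality profile '%s' has no data rows; defaults used everywhere",
                    quality_path))
    return(prof)
  }
  covered <- array(FALSE, dim = c(max_len, 4, 2))
  for (r in seq_len(nrow(df))) {
    mq <- suppressWarnings(as.numeric(df$mean_q[r]))
    sq <- suppressWarnings(as.numeric(df$sd_q[r]))
    if (is.na(mq) || is.na(sq) || sq < 0)
      stop(sprintf("quality profile '%s': bad mean/sd in row %d", quality_path, r),
           call. = FALSE)
    is_err <- as.integer(df$is_error[r]) == 1L
    pos <- expand_wildcard_pos(df$position[r], max_len)
    pos <- pos[pos <= max_len]
    base <- expand_wildcard_base(df$base[r])
    if (is_err) {
      prof$error_mean_q[pos, base] <- mq; prof$error_sd_q[pos, base] <- sq
    } else {
      prof$mean_q[pos, base] <- mq; prof$sd_q[pos, base] <- sq
    }
    covered[pos, base, if (is_err) 2L else 1L] <- TRUE
  }
  if (!all(covered))
    warning(sprintf("quality profile '%s' leaves %d (position, base, class) cells unspecified; defaults used for them",
                    quality_path, sum(!covered)))
  prof
}

#' Write profiles in the package's tab-separated dialect
#'
#' Convenience writers producing files that [load_profiles()] reads back.
#' `write_uniform_profiles()` emits one wildcard row per (quality class),
#' the compactest representation of a flat profile.
#'
#' @param path output file.
#' @param rate flat substitution probability.
#' @param mean_q,sd_q,error_mean_q,error_sd_q flat quality parameters.
#' @return `path`, invisibly.
#' @export
write_uniform_error_profile <- function(path, rate = 1e-3) {
  writeLines(c("position\tref_base\talt_base\tprobability",
               sprintf("*\t*\t*\t%g", rate)), path)
  invisible(path)
}

#' @rdname write_uniform_error_profile
#' @export
write_uniform_quality_profile <- function(path, mean_q = 37, sd_q = 2,
                                          error_mean_q = 25, error_sd_q = 5) {
  writeLines(c("position\tbase\tmean_q\tsd_q\tis_error",
               sprintf("*\t*\t%g\t%g\t0", mean_q, sd_q),
               sprintf("*\t*\t%g\t%g\t1", error_mean_q, error_sd_q)), path)
  invisible(path)
}
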