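#' Fit the feature preprocessing transform on a discovery cohort
#'
#' Freezes, per feature, the coding used by all downstream models:
#' \itemize{
#'   \item binary features (exactly two observed levels, unless declared
#'     otherwise) are mapped to ±1 — the lexicographically larger level
#'     (e.g. `1`, `TRUE`, `"present"`) becomes +1;
#'   \item quantitative features are z-normalized with the mean and sample
#'     standard deviation (n − 1 denominator) of the *discovery* non-missing
#'     values.
#' }
#' Missing values never enter the estimates. Degenerate features — constant
#' quantitative columns, or binary columns with a single observed level —
#' are rejected with an error naming them.
#'
#' @param data Discovery feature table (data frame); non-feature columns
#'   must be dropped or listed in `exclude`.
#' @param types Optional named character vector declaring `"binary"` or
#'   `"quantitative"` per feature; undeclared features are auto-detected
#'   (<= 2 distinct non-missing values means binary). Ordinal covariates
#'   such as Gleason score are treated as quantitative.
#' @param exclude Character vector of column names to ignore.
#' @return A `preprocess_state` object; apply it with [apply_preprocess()].
#' @examples
#' d <- data.frame(htn = c(0, 1, 1), psa = c(1, 2, 3))
#' st <- fit_preprocess(d)
#' apply_preprocess(st, d)
#' @export
fit_preprocess <- function(data, types = NULL, exclude = character()) {
  data <- data[, setdiff(names(data), exclude), drop = FALSE]
  feats <- names(data)
  if (length(feats) == 0) {
    abort("No features left to preprocess.", class = "pwlscore_schema_error")
  }

  state <- vector("list", length(feats))
  names(state) <- feats
  degenerate <- character()

  for (f in feats) {
    v <- data[[f]]
    v_obs <- v[!is.na(v)]
    if (length(v_obs) < 2) {
      degenerate <- c(degenerate, f)
      next
    }
    declared <- if (!is.null(types) && f %in% names(types)) types[[f]] else NA
    lv <- sort(unique(v_obs))
    is_binary <- if (!is.na(declared)) declared == "binary" else length(lv) <= 2

    if (is_binary) {
      if (length(lv) != 2) {
        degenerate <- c(degenerate, f)
        next
      }
      state[[f]] <- list(coding = "binary",
                         neg_level = lv[1], pos_level = lv[2])
    } else {
      if (!is.numeric(v_obs)) {
        abort(sprintf("Quantitative feature `%s` is not numeric.", f),
              class = "pwlscore_schema_error")
      }
      mu <- mean(v_obs)
      s <- sd(v_obs)
      if (!is.finite(s) || s == 0) {
        degenerate <- c(degenerate, f)
        next
      }
      state[[f]] <- list(coding = "quantitative", mean = mu, sd = s)
    }
  }

  if (length(degenerate) > 0) {
    abort(paste0("Degenerate features (constant or single-level): ",
                 paste(degenerate, collapse = ", ")),
          class = "pwlscore_degenerate_feature")
  }
  structure(list(features = state), class = "preprocess_state")
}

#' Apply a fitted preprocessing transform
#'
#' Deterministically transforms a raw feature table with a frozen
#' [fit_preprocess()] state: binary features to ±1, quantitative features
#' to `(x - mean) / sd` with discovery-cohort estimates, and missing values
#' to exactly 0 *after* coding (a missing quantitative value therefore
#' equals the discovery mean in effect).
#'
#' @param state A `preprocess_state`.
#' @param data Raw feature table; must contain every fitted feature.
#' @return A numeric tibble (samples x features) with no non-finite values;
#'   the missingness mask is attached as attribute `missing_mask`.
#' @export
apply_preprocess <- function(state, data) {
  stopifnot(inherits(state, "preprocess_state"))
  feats <- names(state$features)
  missing_feats <- setdiff(feats, names(data))
  if (length(missing_feats) > 0) {
    abort(paste0("Features absent from data: ",
                 paste(missing_feats, collapse = ", ")),
          class = "pwlscore_schema_error")
  }

  n <- nrow(data)
  out <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  mask <- matrix(FALSE, n, length(feats), dimnames = list(NULL, feats))

  for (f in feats) {
    st <- state$features[[f]]
    v <- data[[f]]
    miss <- is.na(v)
    if (st$coding == "binary") {
      z <- numeric(n)
      pos <- !miss & v == st$pos_level
      neg <- !miss & v == st$neg_level
      bad <- !miss & !pos & !neg
      if (any(bad)) {
        abort(sprintf("Feature `%s` has values outside the fitted levels.", f),
              class = "pwlscore_validation_error")
      }
      z[pos] <- 1
      z[neg] <- -1
    } else {
      z <- (as.numeric(v) - st$mean) / st$sd
    }
    z[miss] <- 0
    out[, f] <- z
    mask[, f] <- miss
  }

  res <- tibble::as_tibble(as.data.frame(out))
  attr(res, "missing_mask") <- mask
  res
}

#' @export
print.preprocess_state <- function(x, ...) {
  k <- vapply(x$features, function(f) f$coding, character(1))
  cat("<preprocess_state>", length(k), "features:",
      sum(k == "binary"), "binary,",
      sum(k == "quantitative"), "quantitative\n")
  invisible(x)
}

#' Tidy a preprocessing state into a per-feature table
#'
#' @param x A `preprocess_state`.
#' @param ... Unused.
#' @return Tibble with `feature`, `coding`, `mean`, `sd`, `neg_level`,
#'   `pos_level`.
#' @exportS3Method generics::tidy
tidy.preprocess_state <- function(x, ...) {
  purrr::imap_dfr(x$features, function(st, f) {
    tibble::tibble(
      feature = f, coding = st$coding,
      mean = st$mean %||% NA_real_, sd = st$sd %||% NA_real_,
      neg_level = as.character(st$neg_level %||% NA),
      pos_level = as.character(st$pos_level %||% NA)
    )
  })
}

#' Validate and expose SNP genotypes as quantitative feature columns
#'
#' SNPs are coded additively: the minor-allele count (0, 1 or 2) is treated
#' as a quantitative variable and z-normalized like any other quantitative
#' feature by [fit_preprocess()], so a heterozygote carries one unit of
#' effect and a minor homozygote two.
#'
#' @param genotypes Matrix or data frame of minor-allele counts in
#'   \{0, 1, 2\} (`NA` allowed).
#' @return A tibble of numeric columns suitable for binding to the clinical
#'   feature table.
#' @export
encode_genotypes <- function(genotypes) {
  g <- as.matrix(genotypes)
  vals <- g[!is.na(g)]
  if (length(vals) > 0 && !all(vals %in% c(0, 1, 2))) {
    abort("Genotype values must be minor-allele counts in {0, 1, 2}.",
          class = "pwlscore_validation_error")
  }
  if (is.null(colnames(g))) colnames(g) <- paste0("snp_", seq_len(ncol(g)))
  tibble::as_tibble(as.data.frame(apply(g, 2, as.numeric)))
}

#' Serialize / restore a preprocessing state as JSON
#'
#' Makes the exact frozen transform auditable and portable.
#'
#' @param state A `preprocess_state`.
#' @param path File path.
#' @return `write_preprocess_state()` returns `path` invisibly;
#'   `read_preprocess_state()` returns the restored state.
#' @export
write_preprocess_state <- function(state, path) {
  stopifnot(inherits(state, "preprocess_state"))
  jsonlite::write_json(state$features, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess_state
#' @export
read_preprocess_state <- function(path) {
  feats <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  structure(list(features = feats), class = "preprocess_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
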