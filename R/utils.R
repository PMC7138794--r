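# Internal helpers shared across modules.

# 95% normal quantile used for every confidence interval in the package.
Z95 <- 1.959964

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Two-sided normal p, clamped into (0, 1] so downstream log/FDR steps never
# see an exact zero from tail underflow.
.p_norm2 <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

.p_t2 <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Extract the rows an estimator may consume: either the retained rows of a
# harmonized_set or a plain data.frame already carrying the effect columns.
#' Rows available for estimation
#'
#' Returns the retained (non-dropped) per-SNP rows of a [harmonize()] result,
#' or passes through a data.frame that already has `beta_zx`, `se_zx`,
#' `beta_zy`, `se_zy` columns. Dropped SNPs never reach an estimator.
#'
#' @param h A `harmonized_set` or a data.frame of per-SNP effect estimates.
#' @return A data.frame with one row per usable SNP.
#' @export
mr_rows <- function(h) {
  if (inherits(h, "harmonized_set")) {
    r <- h$rows[h$rows$action %in% c("unchanged", "flipped"), , drop = FALSE]
  } else if (is.data.frame(h)) {
    r <- h
  } else {
    stop("expected a harmonized_set or a data.frame of per-SNP estimates",
         call. = FALSE)
  }
  need <- c("beta_zx", "beta_zy", "se_zy")
  miss <- setdiff(need, names(r))
  .assert(length(miss) == 0,
          paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(r$rsid)) r$rsid <- sprintf("snp%d", seq_len(nrow(r)))
  r
}

.h_meta <- function(h, field, default = NA_character_) {
  if (inherits(h, "harmonized_set")) h[[field]] %||% default else default
}
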