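# Constants for the multitrait-multimethod (MTMM) demonstration.
#
# A classic published 3-trait x 3-method correlation matrix is analysed
# with a correlated trait-correlated method model. The matrix itself is
# not redistributed here; what the workflow needs in addition to it is the
# vector of reported reliabilities and the adjusted main diagonal that
# keeps every error variance positive and consistent with those
# reliabilities.

#' Reliabilities of the nine MTMM indicators
#'
#' Reported reliability estimates for the nine manifest variables of the
#' 3-trait x 3-method demonstration, in indicator order (trait 1..3 within
#' method 1, then methods 2 and 3).
#'
#' @format Numeric vector of length 9.
#' @export
mtmm_reliabilities <- c(0.89, 0.89, 0.76, 0.93, 0.94, 0.84, 0.94, 0.92, 0.85)

#' Adjusted main diagonal for the MTMM correlation matrix
#'
#' Replacement for the unit diagonal of the published correlation matrix,
#' chosen so that fitted error variances stay positive and reflect the
#' complements of [mtmm_reliabilities]. Off-diagonal correlations are left
#' untouched (see [adjust_diagonal()]); in the spirit of a ridge
#' adjustment this alters error components of variances, not the
#' systematic components.
#'
#' @format Numeric vector of length 9.
#' @export
mtmm_adjusted_diagonal <- c(1.145, 1.140, 1.145, 1.005, 0.965, 0.965,
                            0.940, 1.010, 0.980)

#' Specification of the correlated trait-correlated method MTMM model
#'
#' Builds the [cfa_spec()] for the 3-trait x 3-method design: each of the
#' nine indicators loads on its trait and its method factor; all latent
#' variances are identified by the chosen method; only the trait 1-trait 2
#' and method 2-method 3 correlations are free (the remaining latent
#' correlations are fixed at zero), mirroring the reduced model with good
#' fit in the demonstration.
#'
#' Indicator order is trait within method: `m1t1, m1t2, m1t3, m2t1, ...`.
#'
#' @inheritParams cfa_spec
#' @param ... Passed to [cfa_spec()] (`markers`, `p_c`, `target`).
#' @return A `cfa_spec` for 9 indicators and 6 factors (3 traits, 3
#'   methods).
#' @export
mtmm_spec <- function(identification = "reference_group", ...) {
  p <- 9
  traits <- rep(1:3, times = 3)   # trait index of each indicator
  methods <- rep(1:3, each = 3)   # method index of each indicator
  pat <- matrix(0, p, 6)
  for (i in seq_len(p)) {
    pat[i, traits[i]] <- NA_real_       # trait loadings free
    pat[i, 3 + methods[i]] <- NA_real_  # method loadings free
  }
  rownames(pat) <- paste0("m", methods, "t", traits)
  colnames(pat) <- c(paste0("trait", 1:3), paste0("method", 1:3))
  phi_pat <- matrix(0, 6, 6)
  diag(phi_pat) <- NA_real_
  phi_pat[1, 2] <- phi_pat[2, 1] <- NA_real_  # r(trait1, trait2) free
  phi_pat[5, 6] <- phi_pat[6, 5] <- NA_real_  # r(method2, method3) free
  cfa_spec(pat, identification = identification, phi = phi_pat, ...)
}
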