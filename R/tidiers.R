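#' Tidy and glance at fitted result objects
#'
#' broom-style methods: `tidy()` returns a one-row-per-component tibble,
#' `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name oriterscan-tidiers
NULL

#' @rdname oriterscan-tidiers
#' @method tidy rc_result
#' @export
tidy.rc_result <- function(x, ...) {
  tibble::tibble(
    segment = c("origin", "rest"),
    start = c(x$boundary_1, x$boundary_2),
    end = c(x$boundary_2, x$boundary_1),
    mean_coverage = c(x$mean_in, x$mean_out),
    n_bins = c(x$n_in, x$n_out)
  )
}

#' @rdname oriterscan-tidiers
#' @method glance rc_result
#' @export
glance.rc_result <- function(x, ...) {
  tibble::tibble(
    rc = x$Rc,
    boundary_1 = x$boundary_1,
    boundary_2 = x$boundary_2,
    mean_in = x$mean_in,
    mean_out = x$mean_out,
    n_in = x$n_in,
    n_out = x$n_out
  )
}

#' @rdname oriterscan-tidiers
#' @method tidy scenario_lr
#' @export
tidy.scenario_lr <- function(x, ...) {
  tibble::tibble(
    scenario = c("duplication", "deletion"),
    prevalence = c(x$p_dup, x$p_del),
    pmf = c(x$pmf_dup, x$pmf_del)
  )
}

#' @rdname oriterscan-tidiers
#' @method glance scenario_lr
#' @export
glance.scenario_lr <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, pmf_dup = x$pmf_dup,
                 pmf_del = x$pmf_del, ratio = x$ratio)
}

#' @rdname oriterscan-tidiers
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname oriterscan-tidiers
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    s_a = attr(x, "s_a"),
    s_b = attr(x, "s_b"),
    fc_threshold = attr(x, "fc_threshold"),
    p_threshold = attr(x, "p_threshold")
  )
}

#' @rdname oriterscan-tidiers
#' @method tidy domain_partition
#' @export
tidy.domain_partition <- function(x, ...) {
  tibble::tibble(
    domain = rep(c("domain_1", "domain_2"),
                 c(length(x$domain1_bins), length(x$domain2_bins))),
    bin = c(x$domain1_bins, x$domain2_bins)
  )
}

#' @rdname oriterscan-tidiers
#' @method glance domain_partition
#' @export
glance.domain_partition <- function(x, ...) {
  tibble::tibble(
    boundary_1 = x$boundary_1, boundary_2 = x$boundary_2,
    score = x$score, n_bins = x$n_bins
  )
}

#' @rdname oriterscan-tidiers
#' @method glance binpair_matrix
#' @export
glance.binpair_matrix <- function(x, ...) {
  tibble::tibble(
    n_bins = x$n_bins,
    bin_size = x$bin_size,
    correlated_pairs = (sum(x$C) + sum(diag(x$C))) / 2,
    anticorrelated_pairs = (sum(x$A) + sum(diag(x$A))) / 2
  )
}

#' @rdname oriterscan-tidiers
#' @method tidy binpair_matrix
#' @export
tidy.binpair_matrix <- function(x, ...) {
  grid <- tidyr::expand_grid(bin_a = 0:(x$n_bins - 1), bin_b = 0:(x$n_bins - 1))
  dplyr::mutate(grid,
                correlated = as.vector(t(x$C)),
                anticorrelated = as.vector(t(x$A)))
}
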