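#' Brand-extension experiment design arithmetic
#'
#' The paradigm this package targets pairs brand names with product
#' names: every brand is crossed with every product, giving
#' `n_brands * n_products` experimental trials, preceded by a block of
#' practice trials. Epochs are cut around the second stimulus, so the
#' per-epoch sample count follows from the window and sampling rate.
#'
#' @param n_brands number of brand-name stimuli (default 14: the seven
#'   most and seven least familiar brands per participant).
#' @param n_products number of product-name stimuli (default 14).
#' @param n_practice practice trials (default 20).
#' @param sampling_rate Hz (default 1000).
#' @param epoch_window ms relative to stimulus onset (default
#'   `c(-200, 800)`).
#' @return list with `n_experimental` (`n_brands * n_products`),
#'   `n_total` (experimental + practice) and `samples_per_epoch`.
#' @examples
#' experiment_design()  # 196 experimental trials, 216 total, 1000 samples
#' @export
experiment_design <- function(n_brands = 14, n_products = 14,
                              n_practice = 20, sampling_rate = 1000,
                              epoch_window = c(-200, 800)) {
  n_exp <- n_brands * n_products
  list(n_experimental = n_exp,
       n_total = n_exp + n_practice,
       samples_per_epoch = round(diff(epoch_window) / 1000 * sampling_rate))
}
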