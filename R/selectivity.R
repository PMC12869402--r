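#' Orientation and direction selectivity indices per neuron
#'
#' For each neuron, the tuning curve is its time- and variant-averaged
#' response per direction within the base class where its mean response
#' is maximal. Indices follow the circular-variance (vector-sum)
#' convention:
#' \deqn{DSI = |\sum_d r_d e^{i\theta_d}| / \sum_d r_d,\quad
#'       OSI = |\sum_d r_d e^{2i\theta_d}| / \sum_d r_d}
#' so a flat tuning curve scores 0 on both, a single-direction response
#' scores 1 on both, and two equal peaks 180 degrees apart score DSI 0,
#' OSI 1. Neurons with zero total response score 0 on both.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @return data.frame with columns \code{neuron_id}, \code{osi},
#'   \code{dsi}, \code{preferred_class}.
#' @export
selectivityIndices <- function(tensor) {
  a <- activity(tensor)
  sq <- sequenceTable(ensemble(tensor))
  N <- dim(a)[1]
  tavg <- apply(a, c(1, 2), mean)                 # neurons x sequences
  cls <- classNames(ensemble(tensor))
  osi <- dsi <- numeric(N)
  prefClass <- character(N)
  for (n in seq_len(N)) {
    classMean <- vapply(cls, function(cl)
      mean(tavg[n, sq$base_class == cl]), numeric(1))
    best <- cls[which.max(classMean)]
    prefClass[n] <- best
    sel <- sq$base_class == best
    agg <- tapply(tavg[n, sel], sq$direction[sel], mean)
    r <- as.numeric(agg)
    th <- as.numeric(names(agg)) * pi / 180
    tot <- sum(r)
    if (tot <= 0) { osi[n] <- 0; dsi[n] <- 0; next }
    dsi[n] <- Mod(sum(r * exp(1i * th))) / tot
    osi[n] <- Mod(sum(r * exp(2i * th))) / tot
  }
  data.frame(neuron_id = neuronIds(tensor), osi = osi, dsi = dsi,
             preferred_class = prefClass, stringsAsFactors = FALSE)
}
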