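# Shared fixtures built in code.

# Confusion matrix of the published five-class test run (rows = predicted,
# columns = original), used as in-repo input data for the metrics module.
published_confusion <- function() {
  matrix(c(12718L, 134L, 102L, 29L, 18L,
           98L, 469L, 15L, 1L, 0L,
           57L, 3L, 1410L, 6L, 2L,
           20L, 0L, 12L, 125L, 0L,
           57L, 2L, 18L, 0L, 1619L),
         nrow = 5, ncol = 5,
         dimnames = list(predicted = beat_classes(),
                         original = beat_classes()))
}

random_bits <- function(nr, nc, density = 0.5) {
  matrix(as.integer(stats::runif(nr * nc) < density), nr, nc)
}

random_image <- function(side = 32, density = 0.3) {
  random_bits(side, side, density)
}

# build an ecg_record directly from components (for boundary-case tests)
manual_record <- function(samples, r_peaks, labels, fs = 360) {
  structure(list(samples = samples, fs = fs, r_peaks = r_peaks,
                 labels = labels,
                 truncated = rep(FALSE, length(r_peaks)),
                 record_id = "manual", seed = 0L),
            class = "ecg_record")
}

# half-max width of the QRS complex around the annotated peak
qrs_halfmax_width <- function(beat) {
  hm <- max(beat) / 2
  sum(beat[71:131] > hm)
}
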