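# Small hand-built pig-record table for summary-statistic tests.
tiny_records <- function() {
  data.frame(
    pig_id = sprintf("P%02d", 1:8),
    litter_id = rep(c("L1", "L2"), each = 4),
    group = rep(c(1L, 4L), each = 4),
    regime = rep(c("conventional", "welfare_friendly"), each = 4),
    sex = rep(c("M", "F"), 4),
    weaning_weight = c(7, 7.5, 6.8, 7.2, 11, 11.5, 10.8, 11.2),
    slaughter_weight = c(95, 97, 99, NA, 100, 104, 108, 102),
    dead = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    weak_or_dead = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# Herd configuration scaled up to about n pigs per regime (two groups of
# mean litter size 11 per regime).
big_herd_config <- function(n_per_regime, ...) {
  herd_config(litters_per_group = ceiling(n_per_regime / (2 * 11)), ...)
}
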