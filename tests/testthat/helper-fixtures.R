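# shared fixture builders; everything is generated in code

random_mask <- function(side, num_classes, seed) {
  set.seed(seed)
  matrix(sample(0:(num_classes - 1L), side * side, replace = TRUE), side, side)
}

# brute-force one-vs-rest confusion tally, pixel by pixel
oracle_confusion <- function(pred, truth, class_id) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == class_id
      t <- truth[i, j] == class_id
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

tiny_pair <- function(side = 16, seed = 1) {
  set.seed(seed)
  list(image = matrix(runif(side * side), side, side),
       mask = matrix(sample(0:3, side * side, TRUE), side, side))
}
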