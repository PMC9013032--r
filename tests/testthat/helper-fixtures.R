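# Hand-built fixtures small enough to reason about by eye.

tiny_maps <- function() {
  reference_maps(
    body_system = c(I10 = 7L, E8770 = 3L, J9601 = 8L, N170 = 10L,
                    D649 = 4L, Z3800 = 15L, I5023 = 7L, E1122 = 3L),
    ccmcc = c(J9601 = "MCC", N170 = "MCC", I5023 = "MCC",
              E8770 = "CC", E1122 = "CC"),
    elixhauser = data.frame(
      code = c("I10", "E8770", "D649", "I5023", "E1122", "N170"),
      category = c("HTN", "LYTES", "ANEMDEF", "CHF", "DMCX", "RENLFAIL"),
      stringsAsFactors = FALSE),
    poa_exempt = "Z3800",
    version_label = "fixture-1")
}

# dxf("I10","Y","principal", "J9601","N","secondary") -> diagnoses rows
dxf <- function(...) {
  v <- c(...)
  stopifnot(length(v) %% 3 == 0)
  m <- matrix(v, ncol = 3, byrow = TRUE)
  data.frame(code = m[, 1], poa = m[, 2], position = m[, 3],
             stringsAsFactors = FALSE)
}

# Build an encounter_set from a named list of dxf() frames.
make_encset <- function(dx_list, admit_soi = NULL, discharge_soi = NULL,
                        ...) {
  n <- length(dx_list)
  ids <- names(dx_list)
  if (is.null(ids)) ids <- sprintf("E%03d", seq_len(n))
  dx <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- dx_list[[i]]
    if (is.null(d) || !nrow(d)) return(NULL)
    cbind(data.frame(encounter_id = ids[i], stringsAsFactors = FALSE), d)
  }))
  if (is.null(dx)) {
    dx <- data.frame(encounter_id = character(), code = character(),
                     poa = character(), position = character())
  }
  extra <- list(...)
  enc <- data.frame(encounter_id = ids, age = 50, sex = "Female",
                    race = "White", facility = "F01",
                    discharge_month = "2019-01",
                    admit_soi = admit_soi %||% rep(2L, n),
                    discharge_soi = discharge_soi %||% rep(3L, n),
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) enc[[nm]] <- extra[[nm]]
  encounter_set(enc, dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles ------------------------------------------------------

# Mann-Whitney pairwise concordance over all positive-negative pairs.
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Exhaustive scan of every distinct score as cutoff, minimizing the
# distance to the ROC upper-left corner; ties toward larger threshold.
scan_cutoff <- function(scores, labels) {
  cand <- sort(unique(scores), decreasing = TRUE)
  d <- vapply(cand, function(t) {
    tpr <- sum(scores >= t & labels == 1) / sum(labels == 1)
    fpr <- sum(scores >= t & labels == 0) / sum(labels == 0)
    sqrt(fpr^2 + (1 - tpr)^2)
  }, numeric(1))
  cand[which.min(d)]
}

# Direct average-precision step sum by naive counting at each threshold.
ap_oracle <- function(scores, labels) {
  cand <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  rec_prev <- 0
  ap <- 0
  for (t in cand) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    rec <- tp / P
    ap <- ap + (rec - rec_prev) * tp / (tp + fp)
    rec_prev <- rec
  }
  ap
}

# Small default simulation shared by several tests.
small_sim <- function(seed = 7, n = 1500) {
  cfg <- sim_config(seed = seed, n_encounters = n)
  maps <- generate_reference_maps(cfg)
  list(cfg = cfg, maps = maps, enc = generate_encounters(cfg, maps))
}
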