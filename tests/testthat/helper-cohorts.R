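# Shared fixtures: small matrices and cohorts built in code.

# tiny complete proteome_matrix with hand-picked values
toy_matrix <- function(values, ptau = NULL, donor = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", 1:n)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(ptau)) ptau <- rep(c("negative", "positive"), length.out = n)
  if (is.null(donor)) donor <- rep("D1", n)
  proteome_matrix(values,
                  data.frame(sample_id = colnames(values), donor_id = donor,
                             ptau_status = ptau, capture = "single_cell",
                             stringsAsFactors = FALSE))
}

# trajectory over arbitrary values without going through a matrix
toy_trajectory <- function(values, ids = names(values)) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(values))
  names(values) <- ids
  out <- data.frame(sample_id = ids, value = unname(values),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "tau_proxy"
  class(out) <- c("trajectory_result", "data.frame")
  out
}

# cohort at the breakpoint-recovery study conditions: 100 analysed proteins
# of which 20 early-break, 20 late-break, 20 linear up, 20 linear down
recovery_config <- function(seed, n_cells = 200, noise_sd = 0.3) {
  cohort_config(n_cells = n_cells, n_proteins = 101,
                frac_linear_up = 0.2, frac_linear_down = 0.2,
                frac_early_break = 0.2, frac_late_break = 0.2,
                noise_sd = noise_sd, seed = seed)
}

# fully-null cohort (every protein flat apart from donor offsets and noise)
null_config <- function(seed, n_cells = 100, n_proteins = 400) {
  cohort_config(n_cells = n_cells, n_proteins = n_proteins,
                frac_linear_up = 0, frac_linear_down = 0,
                frac_early_break = 0, frac_late_break = 0, seed = seed)
}

# one-record PTM row passing every filter; override fields to violate rules
clean_ptm_record <- function(...) {
  rec <- data.frame(peptide = "AAAPK", site = "T231",
                    site_localization_probability = 1,
                    lib_q_value = 0.1, global_q_value = 0.1,
                    lib_peptidoform_q_value = 0.1,
                    global_peptidoform_q_value = 0.1,
                    q_value = 0.001, pep = 0.01, peptidoform_q_value = 0.001,
                    ptm_site_confidence = 0.99,
                    stringsAsFactors = FALSE)
  over <- list(...)
  rec[names(over)] <- over
  rec
}
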