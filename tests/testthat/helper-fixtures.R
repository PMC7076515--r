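# canonical caffeine-in-water parameters and the 18 h / 120 s sampling grid
caf_params <- function() diffusion_params(A = 111, sigma = 0.11, D = 9.07e-6)

std_times <- function() seq(120, 64800, by = 120)

# all four probe drugs as diffusion_params objects
drug_params_list <- function() {
  d <- reference_drugs()
  setNames(
    lapply(seq_len(nrow(d)), function(i) {
      diffusion_params(A = d$A_0[i], sigma = d$sigma[i], D = d$D_0[i])
    }),
    d$drug)
}
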