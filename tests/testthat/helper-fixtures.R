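# shared fixtures: noise-free device truths and an independent steady-state
# oracle for the nephron chain (forward substitution, written against the
# model equations by hand; the package integrates an ODE instead)

noise_free_truth <- function(cl_transport = 3, cl_passive = 1, seed = 1L) {
  mps_ground_truth(cl_app_transport = cl_transport,
                   cl_app_passive = cl_passive,
                   noise_cv = 0, seed = seed)
}

# algebraic steady state of the series nephron: each segment is well mixed,
# so C_i = (inflow + sources) / (outflow + reabsorption), solved in order
nephron_oracle_clr <- function(drug, phys, c_p = 1000) {
  seg <- phys$segments
  fn <- function(ph) 1 / (1 + 10^(drug$pka_base - ph))
  pa_u <- drug$papp / fn(phys$assay_ph) * 1e-6 * seg$area_cm2 * 3.6
  sec <- numeric(nrow(seg))
  sec[1:3] <- drug$secretion$total / drug$secretion$n_subsegments
  flux <- phys$gfr * 0.06 * drug$fu_p * c_p
  for (i in seq_len(nrow(seg))) {
    ci <- (flux + sec[i] * c_p + pa_u[i] * fn(phys$plasma_ph) * drug$fu_p * c_p) /
      (seg$flow_out_L_h[i] + pa_u[i] * fn(seg$ph[i]))
    flux <- seg$flow_out_L_h[i] * ci
  }
  flux / c_p
}
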