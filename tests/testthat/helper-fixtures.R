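# Fixtures built in code: tiny registries and hand-made profiles.

# Single parent, no metabolism, renal elimination only.  Transit through the
# portal/liver compartments is made effectively instantaneous (huge flows,
# tiny volumes) so the systemic profile admits the one-compartment
# first-order-absorption closed form as an oracle.
one_compartment_registry <- function(ka = 1.2, fa = 0.8, v_sys = 50,
                                     renal_cl = 5) {
  new_registry(
    compounds = list(
      drugx = compound_spec("drugx", molecular_weight = 300, ka = ka,
                            fa = fa, fu_plasma = 1, blood_plasma_ratio = 1,
                            v_sys = v_sys, renal_cl = renal_cl)),
    physiology = physiology_spec(
      q_hepatic_total = 1e4, q_portal = 7.5e3, q_hepatic_arterial = 2.5e3,
      q_gut = 14, liver_weight = 1500, mppgl = 40, gut_protein = 3000,
      v_portal = 1e-5, v_liver = 1e-5),
    pd = pd_spec(kin = 0.0124, kout = 0.0124, kirre = 40, mpa0 = 55))
}

# Parent -> metabolite chain with liver formation, for topology tests.
chain_registry <- function(clint_form = 50, clint_inact = 100,
                           renal_met = 20) {
  new_registry(
    compounds = list(
      parent = compound_spec("parent", molecular_weight = 350, ka = 1,
                             fa = 1, fu_plasma = 0.1, blood_plasma_ratio = 1,
                             v_sys = 100,
                             pathways = list(
                               enzyme_pathway("CYP2C19", "liver", clint_form,
                                              product = "met"),
                               enzyme_pathway("CES1", "liver", clint_inact))),
      met = compound_spec("met", molecular_weight = 350, fu_plasma = 0.1,
                          blood_plasma_ratio = 1, v_sys = 60,
                          renal_cl = renal_met)),
    physiology = physiology_spec(
      q_hepatic_total = 90, q_portal = 67.5, q_hepatic_arterial = 22.5,
      q_gut = 14, liver_weight = 1500, mppgl = 40, gut_protein = 3000,
      v_portal = 1, v_liver = 1.5),
    pd = pd_spec(kin = 0.0124, kout = 0.0124, kirre = 40, mpa0 = 55))
}

# Hand-made concentration profile for driving the PD model directly.
make_profile <- function(times, conc_ng_ml, compound = "AM-H4", mw = 355.9,
                         last_dose = 0) {
  conc <- matrix(rep(conc_ng_ml, length.out = length(times)), ncol = 1,
                 dimnames = list(NULL, compound))
  structure(list(times = times, conc = conc,
                 amounts = matrix(0, length(times), 0),
                 compounds = compound,
                 mw = stats::setNames(mw, compound),
                 v_sys = stats::setNames(1, compound),
                 subject = 0L, arm = "fixture",
                 regimen = data.frame(time_h = last_dose, dose_mg = 1),
                 parent = compound,
                 dosed_nmol = data.frame(time_h = last_dose, nmol = 0),
                 n_core = 0L),
            class = "concentration_profile")
}

ref_registry <- function() default_registry()
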