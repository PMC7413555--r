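# Shared fixtures for solver tests: the three study probes and a per-phase
# curve comparison normalized by the peak force (forces vanish at contact
# and detachment, so pointwise relative error is ill-posed there).

study_probes <- function() list(
  cylinder = probe_geometry("cylinder", radius = 0.4e-6),
  sphere = probe_geometry("sphere", radius = 5e-6),
  cone = probe_geometry("cone", half_angle = 85 * pi / 180)
)

# maximum |F_num - F_ref| / max(F_ref), per phase, with the reference curve
# linearly interpolated onto the numeric timestamps
curve_error <- function(fc, ref) {
  a <- as.data.frame(fc)
  b <- as.data.frame(ref)
  fmax <- max(b$force_N)
  err <- 0
  for (ph in c("approach", "retract")) {
    ia <- a$phase == ph
    ib <- b$phase == ph
    if (!any(ia) || !any(ib)) next
    if (sum(ib) == 1L) next
    f_ref <- approx(b$time_s[ib], b$force_N[ib], xout = a$time_s[ia],
                    rule = 2)$y
    err <- max(err, max(abs(a$force_N[ia] - f_ref)))
  }
  err / fmax
}
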