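# Default log-normal prior for MAP-Bayesian individual estimation.
# Central values are the early-phase cohort medians shipped with the
# package (CL in L/h, Vd in L) with a deliberately wide 50% CV. To
# reproduce the behaviour of a specific TDM software configuration
# (e.g. a literature prior such as Drusano and colleagues' ciprofloxacin
# parameters), supply your own file with the same keys.
cl: 18.59
vd: 136.9
cv_cl: 0.5
cv_vd: 0.5
source: early-phase cohort medians, 50% CV
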