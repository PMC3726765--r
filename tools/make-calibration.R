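# Regenerates the shipped calibration artifact at inst/extdata/.
# Run from the package root: Rscript tools/make-calibration.R
devtools::load_all(".", quiet = TRUE)
cal <- calibrate_coassoc(n_cal = 10000, reps_cal = 500, seed = 101L)
print(cal)
write_calibration(cal, file.path("inst", "extdata", "calibration-default.txt"))
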