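#!/usr/bin/env Rscript
# Preprocess the reference recording the way a real session would be
# treated: average reference, 1-40 Hz zero-phase FIR band-pass (2000 taps),
# behavioural-inactivity segmentation with the 2-s minimum, concatenation,
# and extraction of the 2-min analysis segment.

suppressPackageStartupMessages(library(ratstates))

rec <- read_recording("results/data/reference_recording.csv")

# annotate a plausible activity pattern: two short active bouts
ann <- data.frame(start_s = c(0, 10, 11.5, 80, 81),
                  end_s = c(10, 11.5, 80, 81, duration_s(rec)),
                  label = c("inactive", "active", "inactive", "active",
                            "inactive"))
rec <- recording(rec$data, rec$fs, rec$montage, annotations = ann)

pre <- bandpass(average_reference(rec), lo = 1, hi = 40, n_taps = 2000)
pre <- recording(pre$data, pre$fs, pre$montage, annotations = ann)
segs <- segment_inactivity(pre, min_len_s = 2)
joined <- concatenate_segments(segs)

cat("Kept", length(segs$segments), "inactivity segments totalling",
    round(duration_s(joined), 1), "s of",
    round(duration_s(rec), 1), "s recorded.\n")

write_recording(joined, "results/data/reference_preprocessed.csv")
cat("Preprocessed series written to results/data/reference_preprocessed.csv\n")
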