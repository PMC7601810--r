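# Default experiment configuration for rtscan::run_experiment().
# Every key is optional; omitted keys take these values.
design: sequential        # sequential | weekly
model: one                # one | two compartment low-fidelity model
scenarios: [high, medium, low]
k: [0.0, 0.2, 0.5, 1.0]   # skip-penalty weights to sweep
budget: 12                # scans added by the sequential design
free_tumor: false         # practical variant (two-compartment only)
seeds: [1]
lattice_n: 100            # cellular-automaton lattice side
n_iter: 10000             # DRAM iterations per recalibration
n_mi: 1000                # posterior draws for the MI estimator
k_neighbors: 6            # KSG neighbor order
horizon: 57               # last simulated day
first_treatment_day: 15
n_weeks: 6
dose: 2                   # Gy per fraction
out_dir: null             # directory for history/summary CSVs
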