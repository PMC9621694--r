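file	column	unit	description
loss_log.tsv	step	count	optimization step index (0 = initial state)
loss_log.tsv	sequence	letters	current design sequence (one-letter codes)
loss_log.tsv	loss	nats/weighted	total composite loss (weighted sum of terms)
loss_log.tsv	temperature	loss units	Metropolis temperature at this step (MCMC only)
loss_log.tsv	accepted	boolean	whether the proposal at this step was accepted (MCMC only)
loss_log.tsv	best_loss	nats/weighted	best total loss seen up to this step
loss_log.tsv	certainty	nats	mean pair-distribution Shannon entropy (unweighted term value)
loss_log.tsv	motif_ce	nats	motif distogram cross-entropy (unweighted term value)
loss_log.tsv	motif_rmsd	angstrom	Kabsch-superposed motif backbone RMSD (unweighted term value)
loss_log.tsv	repulsion	probability	mean disallowed cross-chain contact probability in [0,1]
loss_log.tsv	rog	angstrom^2	squared radius-of-gyration excess over rg_max
loss_log.tsv	pae	angstrom	mean predicted aligned error over selected pairs
table.tsv	record	index	input record (structure) index
table.tsv	mask	index	mask window index within the record
table.tsv	start	residues	0-based start of the mask window
table.tsv	length	residues	mask window length
table.tsv	fixed_rmsd	angstrom	Kabsch-superposed backbone RMSD of the unmasked region
table.tsv	seq_recovery	fraction	fraction of masked letters recovered, in [0,1]
table.tsv	masked_plddt	0-100	mean per-residue confidence over the masked region (NA if the completer reports none)
report.tsv	plddt	0-100	mean per-residue prediction confidence over the design
report.tsv	motif_plddt	0-100	mean confidence over motif positions
report.tsv	motif_rmsd	angstrom	motif backbone RMSD, design vs native, after superposition
report.tsv	inter_pae	angstrom	mean predicted aligned error over cross-chain pairs
report.tsv	target_aligned_rmsd	angstrom	binder RMSD after superposing on the target chain only
report.tsv	pass_*	boolean	whether the design passes the matching criterion (strict inequality)
report.tsv	pass	boolean	whether the design passes all criteria
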