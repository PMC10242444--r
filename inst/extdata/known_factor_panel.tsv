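gene	driver_direction	mechanism
Trp53bp1	loss_of_function	HR_restoration
Rif1	loss_of_function	HR_restoration
Mad2l2	loss_of_function	HR_restoration
Shld1	loss_of_function	HR_restoration
Shld2	loss_of_function	HR_restoration
Dynll1	loss_of_function	HR_restoration
Atmin	loss_of_function	HR_restoration
Helb	loss_of_function	HR_restoration
Kmt2c	loss_of_function	HR_restoration
Kmt2d	loss_of_function	HR_restoration
Rad51	gain_of_function	HR_restoration
Ctc1	loss_of_function	fork_stability
Stn1	loss_of_function	fork_stability
Ten1	loss_of_function	fork_stability
Paxip1	loss_of_function	fork_stability
Chd4	loss_of_function	fork_stability
Smarcal1	loss_of_function	fork_stability
Zranb3	loss_of_function	fork_stability
Hltf	loss_of_function	fork_stability
Ezh2	loss_of_function	fork_stability
Mre11a	loss_of_function	fork_stability
Parpbp	loss_of_function	fork_stability
Ccne1	gain_of_function	fork_stability
Parg	loss_of_function	PARP_signaling
Parp1	loss_of_function	PARP_signaling
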