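sample_id,patient_id,stage,locus,tissue_call,ctc_call
LP1,LP1,BT,L858R,+,+
LP1,LP1,BT,T790M,-,-
LP5,LP5,BT,L858R,+,+
LP5,LP5,BT,T790M,-,-
LP6,LP6,BT,L858R,+,+
LP6,LP6,BT,T790M,-,-
LP8,LP8,BT,L858R,+,+
LP8,LP8,BT,T790M,-,-
LP10,LP10,BT,L858R,+,+
LP10,LP10,BT,T790M,-,-
LP12,LP12,BT,L858R,+,+
LP12,LP12,BT,T790M,-,-
LP13,LP13,BT,L858R,+,+
LP13,LP13,BT,T790M,-,-
LP46,LP46,BT,L858R,+,+
LP46,LP46,BT,T790M,-,-
LP47,LP47,BT,L858R,+,+
LP47,LP47,BT,T790M,-,-
LP49-BT,LP49,BT,L858R,+,+
LP49-BT,LP49,BT,T790M,-,-
LP49-AR,LP49,AR,L858R,+,+
LP49-AR,LP49,AR,T790M,+,+
LP2-BT,LP2,BT,19del,+,+
LP2-BT,LP2,BT,T790M,-,-
LP2-AR,LP2,AR,19del,+,+
LP2-AR,LP2,AR,T790M,+,+
LP25,LP25,BT,19del,+,+
LP25,LP25,BT,T790M,-,-
LP43,LP43,BT,19del,+,+
LP43,LP43,BT,T790M,-,-
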