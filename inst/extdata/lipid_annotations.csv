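name,formula,adduct,polarity,role
palmitoylcarnitine,C23H45NO4,[M+H]+,positive,ion
stearoylcarnitine,C25H49NO4,[M+H]+,positive,ion
PI(38:4),C47H83O13P,[M-H]-,negative,ion
PC(34:1),C42H82NO8P,[M+H]+,positive,ion
PC(34:1) sodiated,C42H82NO8P,[M+Na]+,positive,ion
FA(18:1) oleate,C18H34O2,[M-H]-,negative,ion
FA(16:0) palmitate,C16H32O2,[M-H]-,negative,ion
trimethylamine,C3H9N,,both,loss
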