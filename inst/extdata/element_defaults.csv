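element,category,dst_mean,dst_sd,cdst_mean,cdst_sd
framing_performance_test,framing,65.4,23.8,46.7,25.2
framing_behavior_analysis,framing,40.6,27.5,NA,NA
math_overall,math,77.9,18.4,63.6,23.7
math_time_limit,math,88.8,13.5,73.3,21.7
math_input_swap,math,88.6,15.6,NA,NA
math_per_task_feedback,math,67.3,24.0,40.8,27.8
math_difficulty,math,62.8,26.3,42.4,23.0
math_live_comparison,math,59.8,28.5,NA,NA
math_personal_performance,math,58.0,29.0,29.4,22.3
math_front_camera,math,39.7,28.6,NA,NA
speech_overall,speech,46.2,23.3,25.5,19.6
speech_preparation,speech,45.5,25.8,19.6,22.4
speech_time_limits,speech,45.1,27.3,22.6,24.8
speech_questions,speech,43.6,23.8,20.2,22.7
speech_front_camera,speech,37.1,25.9,NA,NA
speech_voice_visualization,speech,30.2,24.2,18.0,21.8
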